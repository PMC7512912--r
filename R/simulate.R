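# Synthetic sequence generators used by the controlled experiments:
# uniform i.i.d. DNA, i.i.d. substitution mutation, block architectures with
# (reverse-complemented) mutated copies, and repeat-rich backbones.

#' Generate a uniform-random DNA sequence
#'
#' i.i.d. symbols, each of A/C/G/T with probability 1/4; deterministic for
#' a given seed.
#'
#' @param n Length (>= 0).
#' @param seed Integer seed.
#' @param id Identifier.
#' @return A [dna_seq()].
#' @export
generate_random <- function(n, seed = 1L, id = "random") {
  stopifnot(n >= 0)
  if (n == 0) return(dna_seq(id, integer()))
  syms <- withr::with_seed(seed, sample.int(4L, n, replace = TRUE) - 1L)
  dna_seq(id, syms)
}

#' Apply i.i.d. substitution mutations
#'
#' Each position is independently selected with probability `rate`; a
#' selected position is replaced by a symbol drawn uniformly from the three
#' *other* symbols, so a selected position always differs from the
#' original. The expected Hamming distance is therefore `rate * length(x)`.
#'
#' @param x A [dna_seq()].
#' @param rate Substitution rate in \[0, 1\].
#' @param seed Integer seed.
#' @return A mutated [dna_seq()] of the same length.
#' @export
mutate_substitutions <- function(x, rate, seed = 1L) {
  stopifnot(inherits(x, "dna_seq"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop("rate must be a fraction in [0, 1]")
  n <- length(x)
  syms <- x$symbols
  if (n > 0 && rate > 0) {
    withr::with_seed(seed, {
      sel <- which(runif(n) < rate)
      if (length(sel)) {
        # offset in {1,2,3} guarantees a different symbol
        off <- sample.int(3L, length(sel), replace = TRUE)
        syms[sel] <- (syms[sel] + off) %% 4L
      }
    })
  }
  dna_seq(paste0(x$id, "_mut"), syms)
}

low_entropy_symbols <- function(len, seed, motif_len = 11L, noise = 0.02) {
  withr::with_seed(seed, {
    motif <- sample.int(4L, motif_len, replace = TRUE) - 1L
    syms <- rep_len(motif, len)
    sel <- which(runif(len) < noise)
    if (length(sel))
      syms[sel] <- (syms[sel] + sample.int(3L, length(sel), replace = TRUE)) %% 4L
    syms
  })
}

#' Construct a block plan
#'
#' A block plan is a tibble describing, in order, the blocks that are
#' concatenated into two output sequences `x` and `y`. Each row gives a
#' block `label`, its `target` (`"x"` or `"y"`), its `length`, a `source`
#' and a substitution `rate`. Sources are `"random"` (uniform i.i.d.),
#' `"low-entropy"` (a short tiled motif with light noise), `"copy:<LABEL>"`
#' (the content of an earlier block, mutated at `rate`), and
#' `"rc-copy:<LABEL>"` (the reverse complement of an earlier block, mutated
#' at `rate`). Copy sources may only reference previously defined labels.
#'
#' @param label,target,length,source,rate Vectors of equal length (or
#'   scalars, recycled) defining one block per element.
#' @return A tibble of class `block_plan`.
#' @seealso [generate_blocks()], [read_block_plan()]
#' @export
block_plan <- function(label, target, length, source, rate = 0) {
  plan <- tibble::tibble(label = as.character(label),
                         target = as.character(target),
                         length = as.integer(length),
                         source = as.character(source),
                         rate = as.numeric(rate))
  validate_block_plan(plan)
  class(plan) <- c("block_plan", class(plan))
  plan
}

validate_block_plan <- function(plan) {
  stopifnot(all(c("label", "target", "length", "source", "rate") %in% names(plan)))
  if (any(plan$length <= 0L)) stop("block lengths must be > 0")
  if (any(plan$rate < 0 | plan$rate > 1)) stop("substitution rates must be in [0, 1]")
  if (!all(plan$target %in% c("x", "y"))) stop("targets must be \"x\" or \"y\"")
  if (anyDuplicated(plan$label)) stop("block labels must be unique")
  is_copy <- grepl("^(rc-)?copy:", plan$source)
  refs <- sub("^(rc-)?copy:", "", plan$source[is_copy])
  for (i in which(is_copy)) {
    ref <- sub("^(rc-)?copy:", "", plan$source[i])
    earlier <- plan$label[seq_len(i - 1L)]
    if (!ref %in% earlier)
      stop("copy source references undefined or later block: ", ref)
  }
  bad <- !is_copy & !plan$source %in% c("random", "low-entropy")
  if (any(bad)) stop("unknown block source: ", plan$source[which(bad)[1]])
  invisible(plan)
}

#' Read / write a block plan as TSV
#'
#' One block per line with columns `label`, `target`, `length`, `source`,
#' `rate`.
#'
#' @param path File path.
#' @return For `read_block_plan`, a [block_plan()].
#' @export
read_block_plan <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  block_plan(df$label, df$target, df$length, df$source, df$rate)
}

#' @rdname read_block_plan
#' @param plan A [block_plan()].
#' @export
write_block_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan)[, c("label", "target", "length",
                                             "source", "rate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a pair of sequences from a block plan
#'
#' Blocks are concatenated in plan order into their target sequences.
#' `copy:` sources apply [mutate_substitutions()] at the block's rate to the
#' referenced block's content; `rc-copy:` additionally reverse-complements.
#' If a copy is longer/shorter than its source, the source content is
#' recycled/truncated to the block length.
#'
#' @param plan A [block_plan()].
#' @param seed Integer seed.
#' @return A list with elements `x` and `y` ([dna_seq()]s) and
#'   `annotations`, a tibble of (label, target, start, end) with 0-based
#'   half-open coordinates within each target.
#' @export
generate_blocks <- function(plan, seed = 1L) {
  validate_block_plan(plan)
  contents <- list()
  out <- list(x = list(), y = list())
  ann <- vector("list", nrow(plan))
  offsets <- c(x = 0L, y = 0L)
  for (i in seq_len(nrow(plan))) {
    b <- plan[i, ]
    bseed <- seed + 7919L * i
    if (b$source == "random") {
      syms <- generate_random(b$length, seed = bseed)$symbols
    } else if (b$source == "low-entropy") {
      syms <- low_entropy_symbols(b$length, seed = bseed)
    } else {
      ref <- sub("^(rc-)?copy:", "", b$source)
      src <- rep_len(contents[[ref]], b$length)
      if (grepl("^rc-copy:", b$source)) src <- rev(3L - src)
      syms <- mutate_substitutions(dna_seq("tmp", src), b$rate,
                                   seed = bseed)$symbols
    }
    contents[[b$label]] <- syms
    tg <- b$target
    out[[tg]] <- c(out[[tg]], list(syms))
    ann[[i]] <- tibble::tibble(label = b$label, target = tg,
                               start = offsets[[tg]],
                               end = offsets[[tg]] + b$length)
    offsets[[tg]] <- offsets[[tg]] + b$length
  }
  list(x = dna_seq("x", unlist(out$x)),
       y = dna_seq("y", unlist(out$y)),
       annotations = dplyr::bind_rows(ann))
}

#' Generate a repeat-rich sequence
#'
#' A uniform-random backbone of length `n` in which `n_copies` substrings
#' of length `copy_len` (taken from random positions of the backbone) are
#' re-pasted at random non-overlapping positions, each copy mutated at
#' `sub_rate`. Emulates repeat-laden genomic sequence.
#'
#' @param n Total length.
#' @param n_copies Number of pasted copies.
#' @param copy_len Length of each copy.
#' @param sub_rate Substitution rate applied to each pasted copy.
#' @param seed Integer seed.
#' @param id Identifier.
#' @param base_probs Optional symbol probabilities (A, C, G, T) for the
#'   backbone. The default `NULL` draws uniformly; real genomic sequence
#'   is not uniform, so experiments emulating it pass a skewed
#'   composition.
#' @return A [dna_seq()].
#' @export
generate_repeat_rich <- function(n, n_copies, copy_len, sub_rate = 0,
                                 seed = 1L, id = "repeat_rich",
                                 base_probs = NULL) {
  stopifnot(n >= 0, n_copies >= 0, copy_len >= 1)
  if (n_copies * copy_len > n) stop("cannot pack copies: n_copies * copy_len > n")
  base <- if (is.null(base_probs)) {
    generate_random(n, seed = seed, id = id)
  } else {
    stopifnot(length(base_probs) == 4, all(base_probs > 0))
    dna_seq(id, withr::with_seed(seed,
      sample.int(4L, n, replace = TRUE, prob = base_probs) - 1L))
  }
  if (n_copies == 0L) return(base)
  syms <- base$symbols
  withr::with_seed(seed + 1L, {
    # non-overlapping paste positions via the gap construction
    m <- n_copies; L <- copy_len
    t <- sort(sample.int(n - m * L + m, m))
    starts <- t + (seq_len(m) - 1L) * (L - 1L)  # 1-based
    src_starts <- sample.int(n - L + 1L, m, replace = TRUE)
    for (j in seq_len(m)) {
      cp <- base$symbols[src_starts[j]:(src_starts[j] + L - 1L)]
      if (sub_rate > 0) {
        sel <- which(runif(L) < sub_rate)
        if (length(sel))
          cp[sel] <- (cp[sel] + sample.int(3L, length(sel), replace = TRUE)) %% 4L
      }
      syms[starts[j]:(starts[j] + L - 1L)] <- cp
    }
  })
  dna_seq(id, syms)
}
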