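#' DNA sequence object
#'
#' A `dna_seq` holds a DNA sequence as integer codes over the 4-letter
#' alphabet (`0=A, 1=C, 2=G, 3=T`), together with an identifier and the
#' 0-based positions at which non-ACGT input characters were replaced
#' during encoding.
#'
#' @param id Single character identifier.
#' @param symbols Integer vector with values in `0:3`.
#' @param replaced Integer vector of 0-based positions that were replaced
#'   on encoding (empty when the input was pure ACGT).
#' @return An object of class `dna_seq`.
#' @examples
#' s <- dna_seq("s1", c(0L, 1L, 2L, 3L))
#' as.character(s)
#' @export
dna_seq <- function(id, symbols, replaced = integer()) {
  stopifnot(is.character(id), length(id) == 1L)
  symbols <- as.integer(symbols)
  if (length(symbols) && (anyNA(symbols) || any(symbols < 0L | symbols > 3L)))
    stop("symbols must be integer codes in {0,1,2,3}")
  replaced <- as.integer(replaced)
  if (length(replaced) && (any(replaced < 0L) || any(replaced >= length(symbols))))
    stop("replaced positions must lie in [0, length)")
  structure(list(id = id, symbols = symbols, replaced = replaced),
            class = "dna_seq")
}

#' @export
length.dna_seq <- function(x) length(x$symbols)

#' @export
print.dna_seq <- function(x, ...) {
  n <- length(x)
  cat("<dna_seq> ", x$id, ": ", n, " bp", sep = "")
  if (length(x$replaced)) cat(" (", length(x$replaced), " replaced)", sep = "")
  cat("\n")
  if (n > 0) {
    shown <- min(n, 60L)
    cat("  ", substr(as.character(x), 1L, shown),
        if (n > shown) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

DNA_LETTERS <- c("A", "C", "G", "T")

#' @export
as.character.dna_seq <- function(x, ...) {
  if (length(x) == 0L) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[x$symbols + 1L])
}

#' Encode a character string into a DNA sequence
#'
#' `A/C/G/T` (case-insensitive) map to codes `0:3`. Every other character
#' is replaced by a symbol drawn uniformly from the alphabet with a
#' deterministic draw keyed on `(seed, position)`, and its 0-based position
#' is recorded in `replaced`, so the same input and seed always encode
#' identically regardless of surrounding context.
#'
#' @param raw Character string (may be empty).
#' @param id Identifier for the resulting sequence.
#' @param seed Integer seed for the replacement draws.
#' @return A [dna_seq()].
#' @examples
#' encode_dna("ACGNNT", seed = 7)
#' @export
encode_dna <- function(raw, id = "seq", seed = 0L) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (nchar(raw) == 0L) return(dna_seq(id, integer()))
  lut <- rep(-1L, 256L)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  codes <- lut[utf8ToInt(raw) + 1L]
  codes[is.na(codes)] <- -1L
  repl <- which(codes < 0L)  # 1-based
  if (length(repl))
    codes[repl] <- encode_replace_cpp(repl - 1L, as.integer(seed))
  dna_seq(id, codes, replaced = repl - 1L)
}

#' Reverse complement of a DNA sequence
#'
#' Complements (`A<->T`, `C<->G`) and reverses.
#'
#' @param x A [dna_seq()].
#' @return A [dna_seq()] with id suffixed `"_rc"`.
#' @export
reverse_complement <- function(x) {
  stopifnot(inherits(x, "dna_seq"))
  dna_seq(paste0(x$id, "_rc"), rev(3L - x$symbols))
}

#' Read DNA sequences from a FASTA file
#'
#' Multi-record, wrapped or single-line FASTA is accepted; record ids are
#' taken from the header up to the first whitespace. Lowercase letters are
#' accepted; non-ACGT characters are replaced per [encode_dna()].
#'
#' @param path Path to a FASTA file.
#' @param seed Seed for non-ACGT replacement draws.
#' @return A list of [dna_seq()] objects, in file order.
#' @export
read_fasta <- function(path, seed = 0L) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(recs))
  purrr::map2(as.character(recs), ids,
              function(s, id) encode_dna(s, id = id, seed = seed))
}

#' Write DNA sequences to a FASTA file
#'
#' Sequences are written wrapped at 70 columns.
#'
#' @param seqs A [dna_seq()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  ss <- Biostrings::DNAStringSet(vapply(seqs, as.character, character(1)))
  names(ss) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
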