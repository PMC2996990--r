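# Shared low-level helpers: seeded RNG scoping, sequence alphabets,
# reverse complement / translation, deterministic text table IO.

#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, runs `code`, and
#' restores the previous state on exit. All stochastic operations in the
#' package route through this so that a single integer seed makes a whole
#' run reproducible without clobbering the user's RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  code
}

DNA_BASES <- c("A", "C", "G", "T")

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Background amino-acid frequencies (Robinson-Robinson style, rounded);
# used only to draw synthetic consensus proteins.
AA_FREQS <- c(A = 0.079, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
              Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
              L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
              S = 0.068, T = 0.059, W = 0.014, Y = 0.032, V = 0.066)

# One representative codon per amino acid for reverse translation, plus stop.
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT",
              `*` = "TAA")

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  # standard table order: third base varies fastest
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

#' Reverse complement of a DNA string
#' @param x character scalar over ACGT.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# Translate a nucleotide string from its first codon until a stop or the end;
# tolerant of lengths that are not multiples of 3 (frameshifted pseudogenes).
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# Reverse-translate a protein with the fixed codon map; appends a stop codon.
reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(aa, names(CODON_OF))
  if (length(bad)) stop("cannot reverse-translate residue(s): ",
                        paste(unique(bad), collapse = ", "))
  paste(c(CODON_OF[aa], CODON_OF[["*"]]), collapse = "")
}

random_protein <- function(length) {
  paste(sample(names(AA_FREQS), length, replace = TRUE, prob = AA_FREQS),
        collapse = "")
}

random_dna <- function(length) {
  if (length <= 0L) return("")
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

# Deterministic TSV writers: fixed column order, no quoting, "." for NA.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#",
             na.strings = ".", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
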