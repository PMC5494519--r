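#' Protein scoring scheme for local alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties. The
#' default is BLOSUM62 with the standard protein gap costs (open 11,
#' extend 1; a gap of length L costs `open + L * extend`). Unknown residues
#' (`X`) score 0 against everything.
#'
#' @param matrix a symmetric integer substitution matrix with residue
#'   rownames, or `"BLOSUM62"` for the built-in default.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return a `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
    aa <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
    matrix <- matrix[aa, aa]
    matrix["X", ] <- 0L
    matrix[, "X"] <- 0L
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, alphabet = rownames(matrix)),
            class = "scoring_scheme")
}

encode_seq <- function(seq, alphabet) {
  if (length(seq) == 1L && nchar(seq) != 1L)
    seq <- strsplit(seq, "")[[1]]
  idx <- match(toupper(seq), alphabet)
  if (anyNA(idx))
    stop("invalid residue(s): ",
         paste(unique(seq[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Exact Smith-Waterman local alignment
#'
#' Affine-gap local alignment by exact dynamic programming (Gotoh), with the
#' coordinates of one optimal aligned segment. Scores are raw (no bit-score
#' conversion); within a fixed scheme raw scores are rank-equivalent to bit
#' scores, which is all the permutation test needs.
#'
#' @param seq_a,seq_b amino-acid strings (or character vectors of residues)
#'   over the scheme's alphabet. Empty sequences score 0 with an empty
#'   segment.
#' @param scheme a [scoring_scheme].
#' @return an `sw_alignment`: `score`, and 1-based segment coordinates
#'   `a_start`, `a_end`, `b_start`, `b_end` (0s when the score is 0).
#' @export
smith_waterman <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  a <- if (length(seq_a) == 1L && !nzchar(seq_a)) integer(0) else
    encode_seq(seq_a, scheme$alphabet)
  b <- if (length(seq_b) == 1L && !nzchar(seq_b)) integer(0) else
    encode_seq(seq_b, scheme$alphabet)
  S <- scheme$matrix
  storage.mode(S) <- "integer"
  res <- sw_align_cpp(a, b, S, as.integer(scheme$gap_open),
                      as.integer(scheme$gap_extend))
  structure(res, class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("sw_alignment: score %d, A[%d..%d] ~ B[%d..%d]\n",
              x$score, x$a_start, x$a_end, x$b_start, x$b_end))
  invisible(x)
}

#' Permutation significance of a local alignment
#'
#' Builds the empirical null the scrambled-protein procedure defines: the
#' observed score is `smith_waterman(A, B)`; the null distribution collects
#' the scores of A against `n_each` composition-preserving random
#' permutations of B and of B against `n_each` permutations of A. The
#' reported `exceed_fraction` is the fraction of null scores greater than
#' or equal to the observed score.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param n_each scrambles per direction (>= 1); the null has `2 * n_each`
#'   scores.
#' @param scheme a [scoring_scheme].
#' @param seed integer seed for the shuffles.
#' @return a `perm_test_result`: `observed` (an `sw_alignment`),
#'   `null_scores`, `exceed_fraction`, `n_each`, `seed`.
#' @export
scramble_test <- function(seq_a, seq_b, n_each = 100L,
                          scheme = scoring_scheme(), seed = 1L) {
  stopifnot(n_each >= 1L)
  obs <- smith_waterman(seq_a, seq_b, scheme)
  a <- encode_seq(seq_a, scheme$alphabet)
  b <- encode_seq(seq_b, scheme$alphabet)
  S <- scheme$matrix
  storage.mode(S) <- "integer"
  go <- as.integer(scheme$gap_open); ge <- as.integer(scheme$gap_extend)
  set.seed(seed)
  null_scores <- c(
    vapply(seq_len(n_each), function(i) {
      sw_align_cpp(a, b[sample.int(length(b))], S, go, ge)$score
    }, numeric(1)),
    vapply(seq_len(n_each), function(i) {
      sw_align_cpp(a[sample.int(length(a))], b, S, go, ge)$score
    }, numeric(1)))
  structure(list(observed = obs, null_scores = null_scores,
                 exceed_fraction = mean(null_scores >= obs$score),
                 n_each = as.integer(n_each), seed = as.integer(seed)),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "perm_test_result: observed score %d; %d/%d null scores >= observed (%.1f%%)\n",
    x$observed$score, sum(x$null_scores >= x$observed$score),
    length(x$null_scores), 100 * x$exceed_fraction))
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
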