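#' Chou-Fasman alpha-helix conformational parameters
#'
#' The classic per-residue helix propensities (P-alpha): dimensionless,
#' higher values favor helix (Glu 1.51, Met 1.45, Ala 1.42 ... Gly 0.57,
#' Pro 0.57).  `X` (unknown residue) maps to the table mean.  These
#' constants back the helix-13 rule of the classifier: the PTC-exclusive
#' C-terminal helix shows high predicted helix propensity, so the
#' signature match is only accepted in a helix-favoring context.
#'
#' @return Named numeric vector over the 20 standard residues plus `X`.
#' @export
chou_fasman_table <- function() {
  tab <- c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
           G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
           M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
           S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)
  c(tab, X = mean(tab))
}

#' Read a user propensity table from delimited text
#'
#' Two whitespace- or tab-delimited columns: one-letter residue, value.
#' All 20 standard residues must be present with finite positive values;
#' `X` is filled with the table mean if absent.
#'
#' @param path Path to the table file.
#' @return Named numeric vector as in [chou_fasman_table()].
#' @export
read_propensity_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("residue", "value"))
  tab <- stats::setNames(as.numeric(df$value), toupper(df$residue))
  missing <- setdiff(AA_STANDARD, names(tab))
  if (length(missing))
    stop("propensity table missing residues: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tab)) || any(tab <= 0))
    stop("propensity values must be finite and positive", call. = FALSE)
  if (!"X" %in% names(tab)) tab <- c(tab, X = mean(tab[AA_STANDARD]))
  tab[AA_ALPHABET]
}

#' Per-residue helix propensity scores
#'
#' @param seq A `seq_record` or residue string.
#' @param table Propensity table (default [chou_fasman_table()]).
#' @return Numeric vector, one score per residue.
#' @export
residue_scores <- function(seq, table = chou_fasman_table()) {
  if (is.character(seq)) seq <- seq_record("query", seq)
  unname(table[strsplit(seq$residues, "")[[1]]])
}

#' Mean score over a closed window
#'
#' @param scores Numeric score vector.
#' @param start,end 1-based closed interval within the vector.
#' @return Arithmetic mean of `scores[start:end]`.
#' @export
window_mean <- function(scores, start, end) {
  n <- length(scores)
  if (!(start >= 1L && start <= end && end <= n))
    stop("window [", start, ", ", end, "] out of range 1..", n,
         call. = FALSE)
  mean(scores[start:end])
}
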