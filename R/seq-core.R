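AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Create a sequence record
#'
#' A `seq_record` holds one identified amino-acid sequence: an accession-like
#' id, a free-text description and a string of one-letter residue codes.
#' Residues are uppercased and validated against the 20 standard amino acids
#' plus `X` (unknown).  Positions are 1-based throughout the package, matching
#' the *E. faecalis* putrescine transcarbamylase numbering used by all
#' signature rules (e.g. STRT at 52, HCLP at 268).
#'
#' @param id Accession-like token (single string, no whitespace).
#' @param residues One-letter amino-acid string; lower case accepted.
#' @param description Optional free-text description.
#' @return An object of class `seq_record` with elements `id`, `description`,
#'   `residues` and `length`.
#' @examples
#' r <- seq_record("toy1", "MSTRTAAK")
#' r$length
#' @export
seq_record <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]+", "", residues))
  if (!nzchar(residues))
    stop("sequence '", id, "': residues must be non-empty", call. = FALSE)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop("sequence '", id, "': invalid residue '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  structure(
    list(id = id, description = description, residues = residues,
         length = nchar(residues)),
    class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id, " (", x$length, " aa)\n", sep = "")
  if (nzchar(x$description)) cat("  ", x$description, "\n", sep = "")
  head <- substr(x$residues, 1, 60)
  cat("  ", head, if (x$length > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and validates each record into a
#' [seq_record()].  Header tokens before the first whitespace become ids;
#' the remainder becomes the description.  Line wrapping and trailing
#' whitespace are normalized; residues are uppercased.
#'
#' @param path Path to an existing FASTA file.
#' @return List of `seq_record` objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  aas <- Biostrings::readBStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(aas)
  lapply(seq_along(aas), function(i) {
    h <- headers[i]
    id <- sub("\\s.*$", "", h)
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    seq_record(id, as.character(aas[[i]]), desc)
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records List of `seq_record` objects.
#' @param path Output path.
#' @param width Maximum body line width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    stopifnot(inherits(r, "seq_record"))
    header <- if (nzchar(r$description))
      paste0(">", r$id, " ", r$description) else paste0(">", r$id)
    writeLines(header, con)
    starts <- seq(1L, r$length, by = width)
    writeLines(substring(r$residues, starts,
                         pmin(starts + width - 1L, r$length)), con)
  }
  invisible(path)
}

# BLOSUM62 with X treated as scoring zero against everything: X is an unknown
# residue, so it neither rewards nor penalizes a column.
alignment_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

#' Globally align two sequences and compute identity/similarity
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed with
#' [Biostrings::pairwiseAlignment()].  A gap run of length L costs
#' `gap_open + L * gap_extend`.  Percent identity is computed over aligned
#' residue pairs (columns where both sequences have a residue); percent
#' similarity additionally counts pairs with a positive substitution-matrix
#' score.  `X` scores zero against everything, so it never counts as
#' identical or similar.
#'
#' The defaults (BLOSUM62, gap open 10, extend 0.5) are the package's pinned
#' parameterization for reproducing family-level identity figures such as the
#' ~43% identity / ~74% identity+similarity between PTC and *P. furiosus* OTC.
#'
#' @param a,b `seq_record` objects (or raw residue strings).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Substitution matrix; default BLOSUM62 with zeroed `X`.
#' @return A `pairwise_alignment` object: `aligned_a`, `aligned_b`, `score`,
#'   `pct_identity`, `pct_similarity`, `overlap_length`.
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 0.5,
                       matrix = alignment_matrix()) {
  if (is.character(a)) a <- seq_record("a", a)
  if (is.character(b)) b <- seq_record("b", b)
  for (r in list(a, b))
    if (!grepl("[^X]", r$residues))
      stop("sequence '", r$id, "' contains only X; cannot align",
           call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  paired <- ca != "-" & cb != "-"
  n <- sum(paired)
  ident <- sum(paired & ca == cb & ca != "X")
  simil <- sum(vapply(which(paired), function(i) {
    if (ca[i] == cb[i] && ca[i] != "X") return(TRUE)
    matrix[ca[i], cb[i]] > 0
  }, logical(1)))
  structure(
    list(aligned_a = ga, aligned_b = gb, score = Biostrings::score(pa),
         pct_identity = 100 * ident / n, pct_similarity = 100 * simil / n,
         overlap_length = n),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", format(x$score),
      ", identity ", sprintf("%.1f%%", x$pct_identity),
      ", identity+similarity ", sprintf("%.1f%%", x$pct_similarity),
      " over ", x$overlap_length, " aligned pairs\n", sep = "")
  invisible(x)
}
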