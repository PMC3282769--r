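#' Parse a degenerate motif in signature notation
#'
#' Patterns use the notation of family signature figures: a bare capital
#' letter is an invariant (predominant) residue, `X` is a wildcard matching
#' any residue, and a parenthesized slash-separated group lists alternatives
#' where capitals mark predominant residues and lower case marks residues
#' occurring at lower frequency.  Examples from the transcarbamylase family:
#' `"STRT"`, `"HCLP"`, `"(Y/W)(G/W)(V/L/I)X"` (the PTC 230 loop) and
#' `"(L/f/v/i/m)XX(F/Y/L/M/v)(L/i/m)"` (the helix-13 signature).
#'
#' @param text Pattern string in signature notation.
#' @param id Optional pattern id; defaults to the notation itself.
#' @return A `motif_pattern`: list with `id`, `source_text` and `positions`,
#'   each position a list with `primary`, `secondary` (character vectors of
#'   residues) and `wildcard` (flag).
#' @export
parse_pattern <- function(text, id = text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  positions <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "X") {
      positions[[length(positions) + 1L]] <-
        list(primary = character(), secondary = character(), wildcard = TRUE)
      i <- i + 1L
    } else if (grepl("^[A-WYZ]$", ch)) {
      if (!ch %in% AA_STANDARD)
        stop("pattern parse error at offset ", i, ": '", ch,
             "' is not a standard residue", call. = FALSE)
      positions[[length(positions) + 1L]] <-
        list(primary = ch, secondary = character(), wildcard = FALSE)
      i <- i + 1L
    } else if (ch == "(") {
      close <- NA_integer_
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == "(")
          stop("pattern parse error at offset ", j,
               ": nested parenthesis", call. = FALSE)
        if (chars[j] == ")") { close <- j; break }
      }
      if (is.na(close))
        stop("pattern parse error at offset ", i,
             ": unbalanced parenthesis", call. = FALSE)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      alts <- strsplit(body, "/", fixed = TRUE)[[1]]
      if (length(alts) == 0L || any(!nzchar(alts)) || grepl("^/|//|/$", body))
        stop("pattern parse error at offset ", i,
             ": empty alternative in group", call. = FALSE)
      if (any(nchar(alts) != 1L))
        stop("pattern parse error at offset ", i,
             ": alternatives must be single residues", call. = FALSE)
      up <- alts == toupper(alts)
      primary <- toupper(alts[up])
      secondary <- toupper(alts[!up])
      if (any(!c(primary, secondary) %in% AA_STANDARD))
        stop("pattern parse error at offset ", i,
             ": non-residue character in group", call. = FALSE)
      if (length(primary) == 0L)
        stop("pattern parse error at offset ", i,
             ": group needs at least one predominant (capital) residue",
             call. = FALSE)
      if (length(intersect(primary, secondary)))
        stop("pattern parse error at offset ", i,
             ": residue listed as both predominant and low-frequency",
             call. = FALSE)
      positions[[length(positions) + 1L]] <-
        list(primary = primary, secondary = secondary, wildcard = FALSE)
      i <- close + 1L
    } else {
      stop("pattern parse error at offset ", i, ": unexpected character '",
           ch, "'", call. = FALSE)
    }
  }
  if (length(positions) == 0L)
    stop("pattern has no positions", call. = FALSE)
  structure(list(id = id, source_text = text, positions = positions),
            class = "motif_pattern")
}

#' Render a motif pattern back to its notation string
#'
#' Inverse of [parse_pattern()]: `render_pattern(parse_pattern(x)) == x`
#' for any pattern written in canonical notation (groups listed capitals
#' first, in original order).
#'
#' @param pattern A `motif_pattern`.
#' @return The notation string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  paste(vapply(pattern$positions, function(p) {
    if (p$wildcard) return("X")
    if (length(p$primary) == 1L && length(p$secondary) == 0L)
      return(p$primary)
    paste0("(", paste(c(p$primary, tolower(p$secondary)), collapse = "/"), ")")
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", x$id, ": ", x$source_text, " (",
      length(x$positions), " positions)\n", sep = "")
  invisible(x)
}

position_matches <- function(spec, residue) {
  if (spec$wildcard) return(TRUE)
  if (residue == "X") return(FALSE)   # unknown residue satisfies only wildcards
  residue %in% spec$primary || residue %in% spec$secondary
}

#' Scan a sequence for occurrences of a degenerate motif
#'
#' Reports every start offset (optionally restricted to a 1-based closed
#' window) at which all pattern positions are satisfied.  A residue satisfies
#' a position if it is in the primary or the secondary set, or the position
#' is a wildcard; a sequence `X` satisfies only wildcards.  Each match
#' carries `primary_fraction`, the fraction of non-wildcard positions matched
#' by a predominant residue, so callers can prefer stronger matches.
#'
#' @param seq A `seq_record` or residue string.
#' @param pattern A `motif_pattern` or notation string.
#' @param window Optional `c(start, end)` 1-based closed interval; matches
#'   must lie fully inside it.
#' @return data.frame with columns `pattern_id`, `start`, `end`, `matched`,
#'   `primary_fraction` (zero rows when nothing matches).
#' @export
scan_motif <- function(seq, pattern, window = NULL) {
  if (is.character(seq)) seq <- seq_record("query", seq)
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  chars <- strsplit(seq$residues, "")[[1]]
  plen <- length(pattern$positions)
  lo <- 1L; hi <- seq$length
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    lo <- as.integer(window[1]); hi <- as.integer(window[2])
    if (lo < 1L || hi > seq$length || lo > hi)
      stop("window [", lo, ", ", hi, "] out of sequence bounds 1..",
           seq$length, call. = FALSE)
  }
  hits <- list()
  nonwild <- !vapply(pattern$positions, `[[`, logical(1), "wildcard")
  last_start <- hi - plen + 1L
  if (last_start >= lo) for (s in lo:last_start) {
    ok <- TRUE
    nprim <- 0L
    for (k in seq_len(plen)) {
      spec <- pattern$positions[[k]]
      res <- chars[s + k - 1L]
      if (!position_matches(spec, res)) { ok <- FALSE; break }
      if (!spec$wildcard && res %in% spec$primary) nprim <- nprim + 1L
    }
    if (ok) {
      pf <- if (any(nonwild)) nprim / sum(nonwild) else 1
      hits[[length(hits) + 1L]] <- data.frame(
        pattern_id = pattern$id, start = s, end = s + plen - 1L,
        matched = substr(seq$residues, s, s + plen - 1L),
        primary_fraction = pf, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(pattern_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      primary_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}
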