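#' Default classifier configuration
#'
#' Windows, thresholds and patterns for the PTC/OTC signature rules, stored
#' as the literal signature notation strings.  Elements:
#' \describe{
#'   \item{strt, hclp, hpxq}{Anchor tetrapeptide patterns (`"STRT"`,
#'     `"HCLP"`, `"HPXQ"`); STRT binds carbamylphosphate, HCLP the amine
#'     substrate, HPXQ is shared family-level evidence.}
#'   \item{spacing_window}{Allowed `hclp_start - strt_start` spacing
#'     (default 190..240; the *E. faecalis* PTC spacing is 268-52 = 216).}
#'   \item{loop_ptc, loop_otc}{230-loop patterns: PTC
#'     `"(Y/W)(G/W)(V/L/I)X"` vs the OTC SMG loop `"XSMG"`.}
#'   \item{loop_offsets}{Search offsets upstream of HCLP for 230-loop
#'     pattern starts (default 50..28 residues upstream; the *E. faecalis*
#'     offset is 38).}
#'   \item{tail_ptc_min, tail_otc_max}{C-terminal tail length thresholds
#'     past the end of HCLP (PTC tails are about 20 residues longer).}
#'   \item{helix13}{C-terminal helix signature
#'     `"(L/f/v/i/m)XX(F/Y/L/M/v)(L/i/m)"`.}
#'   \item{helix13_region}{Length of the C-terminal region scanned
#'     (default 30).}
#'   \item{helix13_window, helix13_threshold}{Helix-propensity window length
#'     and minimum window mean for a helix-favoring context.}
#' }
#'
#' @return Named list of configuration values.
#' @export
classifier_config <- function() {
  list(
    strt = "STRT",
    hclp = "HCLP",
    hpxq = "HPXQ",
    spacing_window = c(190L, 240L),
    loop_ptc = "(Y/W)(G/W)(V/L/I)X",
    loop_otc = "XSMG",
    loop_offsets = c(50L, 28L),
    tail_ptc_min = 60L,
    tail_otc_max = 55L,
    helix13 = "(L/f/v/i/m)XX(F/Y/L/M/v)(L/i/m)",
    helix13_region = 30L,
    helix13_window = 15L,
    helix13_threshold = 1.05
  )
}

rule_outcome <- function(rule_id, status, evidence = "", note = "") {
  stopifnot(status %in% c("ptc_like", "otc_like", "absent", "inapplicable"))
  list(rule_id = rule_id, status = status, evidence = evidence, note = note)
}

#' Locate the invariant STRT/HCLP anchor pair
#'
#' PTC and OTC sequences share the invariant STRT (carbamylphosphate
#' binding) and HCLP (amine binding) tetrapeptides.  Among all matches of
#' both, the leftmost pair whose spacing `hclp_start - strt_start` falls in
#' the configured family window is selected.  The shared HPXQ motif, when
#' found between the anchors, is reported as family-level evidence only.
#'
#' @param seq A `seq_record` or residue string.
#' @param config See [classifier_config()].
#' @return List `anchor_set`: `strt_start`, `hclp_start`, `hpxq_start`
#'   (each `NA` when absent).
#' @export
locate_anchors <- function(seq, config = classifier_config()) {
  if (is.character(seq)) seq <- seq_record("query", seq)
  strt_hits <- scan_motif(seq, config$strt)$start
  hclp_hits <- scan_motif(seq, config$hclp)$start
  strt_start <- NA_integer_; hclp_start <- NA_integer_
  if (length(strt_hits) && length(hclp_hits)) {
    found <- FALSE
    for (s in strt_hits) {
      for (h in hclp_hits) {
        sp <- h - s
        if (sp >= config$spacing_window[1] && sp <= config$spacing_window[2]) {
          strt_start <- s; hclp_start <- h; found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  hpxq_start <- NA_integer_
  if (!is.na(strt_start)) {
    hp <- scan_motif(seq, config$hpxq)$start
    hp <- hp[hp > strt_start & hp < hclp_start]
    if (length(hp)) hpxq_start <- hp[1]
  }
  structure(list(strt_start = strt_start, hclp_start = hclp_start,
                 hpxq_start = hpxq_start),
            class = "anchor_set")
}

#' Signature rule: lysine two residues upstream of STRT
#'
#' OTCs carry a lysine two residues upstream of the STRT motif (it ion-pairs
#' the alpha-carboxylate of ornithine); PTCs replace it, typically by
#' glutamine.  Lysine at `strt_start - 2` is OTC-like; anything else is
#' PTC-like.
#'
#' @param seq `seq_record`.
#' @param anchors An `anchor_set` from [locate_anchors()].
#' @param config See [classifier_config()].
#' @return A rule outcome (list: `rule_id`, `status`, `evidence`, `note`).
#' @export
rule_lysine_upstream <- function(seq, anchors, config = classifier_config()) {
  s <- anchors$strt_start
  if (is.na(s))
    return(rule_outcome("lysine_upstream", "inapplicable",
                        note = "no STRT anchor"))
  if (s < 3L)
    return(rule_outcome("lysine_upstream", "inapplicable",
                        note = "STRT too close to N-terminus"))
  res <- substr(seq$residues, s - 2L, s - 2L)
  status <- if (res == "K") "otc_like" else "ptc_like"
  rule_outcome("lysine_upstream", status,
               evidence = sprintf("%s%d", res, s - 2L))
}

loop_scan_window <- function(anchors, config, pattern_len, seq_len) {
  h <- anchors$hclp_start
  lo <- h - config$loop_offsets[1]
  hi <- h - config$loop_offsets[2] + pattern_len - 1L
  if (lo < 1L || hi > seq_len) return(NULL)
  c(lo, hi)
}

#' Signature rule: 230 loop vs SMG loop
#'
#' About 40 residues upstream of HCLP, OTCs carry the characteristic xSMG
#' sequence (the SMG loop) whereas PTCs carry the specificity-determining
#' 230-loop pattern `(Y/W)(G/W)(V/L/I)X`.  The window upstream of HCLP is
#' scanned for both; finding only the PTC pattern is PTC-like, only xSMG is
#' OTC-like, and both or neither leaves the rule undecided (`absent`).
#'
#' @inheritParams rule_lysine_upstream
#' @return A rule outcome.
#' @export
rule_230_loop <- function(seq, anchors, config = classifier_config()) {
  h <- anchors$hclp_start
  if (is.na(h))
    return(rule_outcome("loop230", "inapplicable", note = "no HCLP anchor"))
  ptc_pat <- parse_pattern(config$loop_ptc, id = "loop_ptc")
  otc_pat <- parse_pattern(config$loop_otc, id = "loop_otc")
  w_ptc <- loop_scan_window(anchors, config, length(ptc_pat$positions),
                            seq$length)
  w_otc <- loop_scan_window(anchors, config, length(otc_pat$positions),
                            seq$length)
  if (is.null(w_ptc) || is.null(w_otc))
    return(rule_outcome("loop230", "inapplicable",
                        note = "loop window out of sequence bounds"))
  ptc_hits <- scan_motif(seq, ptc_pat, w_ptc)
  otc_hits <- scan_motif(seq, otc_pat, w_otc)
  has_ptc <- nrow(ptc_hits) > 0L
  has_otc <- nrow(otc_hits) > 0L
  if (has_ptc && !has_otc) {
    best <- ptc_hits[order(-ptc_hits$primary_fraction, ptc_hits$start), ][1, ]
    rule_outcome("loop230", "ptc_like",
                 evidence = sprintf("%s@%d", best$matched, best$start))
  } else if (has_otc && !has_ptc) {
    rule_outcome("loop230", "otc_like",
                 evidence = sprintf("%s@%d", otc_hits$matched[1],
                                    otc_hits$start[1]))
  } else if (has_ptc && has_otc) {
    rule_outcome("loop230", "absent",
                 note = "both loop variants found in window")
  } else {
    rule_outcome("loop230", "absent",
                 note = "neither loop variant found in window")
  }
}

#' Signature rule: ~20-residue C-terminal extension
#'
#' PTCs carry a C-terminal extension of roughly 20 residues relative to
#' OTCs.  The tail length past the end of HCLP (`length - hclp_start - 3`)
#' is PTC-like at or above `tail_ptc_min`, OTC-like at or below
#' `tail_otc_max`, and undecided in between.
#'
#' @inheritParams rule_lysine_upstream
#' @return A rule outcome.
#' @export
rule_cterm_extension <- function(seq, anchors, config = classifier_config()) {
  h <- anchors$hclp_start
  if (is.na(h))
    return(rule_outcome("cterm_extension", "inapplicable",
                        note = "no HCLP anchor"))
  tail_len <- seq$length - (h + 3L)
  status <- if (tail_len >= config$tail_ptc_min) "ptc_like"
            else if (tail_len <= config$tail_otc_max) "otc_like"
            else "absent"
  rule_outcome("cterm_extension", status,
               evidence = sprintf("tail=%d", tail_len),
               note = if (status == "absent") "tail length ambiguous" else "")
}

#' Signature rule: C-terminal helix-13 signature
#'
#' The PTC-exclusive C-terminal helix carries a weakly diagnostic but
#' constant signature, `(L/f/v/i/m)XX(F/Y/L/M/v)(L/i/m)`, in a region of
#' high predicted alpha-helix propensity.  The rule is PTC-like when the
#' signature matches within the C-terminal region (default last 30
#' residues) and the mean Chou-Fasman propensity over a 15-residue window
#' covering the match exceeds the threshold; otherwise the trait is absent.
#' Multiple matches are resolved by highest primary fraction, then leftmost.
#'
#' @inheritParams rule_lysine_upstream
#' @param table Helix propensity table (default [chou_fasman_table()]).
#' @return A rule outcome.
#' @export
rule_helix13 <- function(seq, anchors, config = classifier_config(),
                         table = chou_fasman_table()) {
  region_len <- config$helix13_region
  if (seq$length < region_len)
    return(rule_outcome("helix13", "inapplicable",
                        note = "sequence shorter than C-terminal region"))
  lo <- seq$length - region_len + 1L
  hits <- scan_motif(seq, parse_pattern(config$helix13, id = "helix13"),
                     window = c(lo, seq$length))
  if (nrow(hits) == 0L)
    return(rule_outcome("helix13", "absent",
                        note = "no signature match in C-terminal region"))
  hits <- hits[order(-hits$primary_fraction, hits$start), ]
  best <- hits[1, ]
  scores <- residue_scores(seq, table)
  half <- (config$helix13_window - (best$end - best$start + 1L)) %/% 2L
  wlo <- max(1L, best$start - half)
  whi <- min(seq$length, wlo + config$helix13_window - 1L)
  wlo <- max(1L, whi - config$helix13_window + 1L)
  prop <- window_mean(scores, wlo, whi)
  if (prop > config$helix13_threshold)
    rule_outcome("helix13", "ptc_like",
                 evidence = sprintf("%s@%d,prop=%.2f", best$matched,
                                    best$start, prop))
  else
    rule_outcome("helix13", "absent",
                 evidence = sprintf("%s@%d,prop=%.2f", best$matched,
                                    best$start, prop),
                 note = "signature context not helix-favoring")
}

#' Classify a sequence as PTC, OTC or neither
#'
#' Combines the five signature rules.  No qualifying STRT/HCLP anchor pair
#' means the sequence is not recognized as a transcarbamylase.  With anchors
#' present, all five rules PTC-like yields a PTC verdict; the three
#' OTC-discriminant rules (lysine upstream, 230 loop, C-terminal tail) all
#' OTC-like yields OTC; anything else is an unclassified transcarbamylase.
#' Full per-rule evidence is always attached.
#'
#' @param seq `seq_record` or residue string.
#' @param config See [classifier_config()].
#' @return A `classification_report`: `record_id`, `verdict`, `anchors`,
#'   `outcomes` (named list of rule outcomes), `score` (count of PTC-like
#'   rules).
#' @export
classify <- function(seq, config = classifier_config()) {
  if (is.character(seq)) seq <- seq_record("query", seq)
  anchors <- locate_anchors(seq, config)
  if (is.na(anchors$strt_start) || is.na(anchors$hclp_start)) {
    anchors_oc <- rule_outcome("anchors", "absent",
                               note = "no STRT/HCLP pair at family spacing")
  } else {
    anchors_oc <- rule_outcome(
      "anchors", "ptc_like",
      evidence = sprintf("STRT@%d,HCLP@%d,spacing=%d", anchors$strt_start,
                         anchors$hclp_start,
                         anchors$hclp_start - anchors$strt_start),
      note = "family anchors (shared with OTC)")
  }
  outcomes <- list(
    anchors = anchors_oc,
    lysine_upstream = rule_lysine_upstream(seq, anchors, config),
    loop230 = rule_230_loop(seq, anchors, config),
    cterm_extension = rule_cterm_extension(seq, anchors, config),
    helix13 = rule_helix13(seq, anchors, config))
  statuses <- vapply(outcomes, `[[`, character(1), "status")
  score <- sum(statuses == "ptc_like")
  verdict <- if (anchors_oc$status == "absent") {
    "NOT_TRANSCARBAMYLASE"
  } else if (all(statuses == "ptc_like")) {
    "PTC"
  } else if (statuses["lysine_upstream"] == "otc_like" &&
             statuses["loop230"] == "otc_like" &&
             statuses["cterm_extension"] == "otc_like") {
    "OTC"
  } else {
    "TRANSCARBAMYLASE_UNCLASSIFIED"
  }
  structure(list(record_id = seq$id, verdict = verdict, anchors = anchors,
                 outcomes = outcomes, score = score),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> ", x$record_id, ": ", x$verdict,
      " (score ", x$score, "/5)\n", sep = "")
  for (oc in x$outcomes)
    cat(sprintf("  %-16s %-12s %s %s\n", oc$rule_id, oc$status,
                oc$evidence, if (nzchar(oc$note)) paste0("[", oc$note, "]")
                else ""))
  invisible(x)
}

#' Classify many records into a tabular report
#'
#' @param records List of `seq_record` objects (e.g. from [read_fasta()]).
#' @param config See [classifier_config()].
#' @return data.frame with one row per record: id, verdict, anchor
#'   positions, per-rule status and evidence columns, and score.
#' @export
classify_records <- function(records, config = classifier_config()) {
  rows <- lapply(records, function(r) {
    rep <- classify(r, config)
    oc <- rep$outcomes
    data.frame(
      record_id = rep$record_id, verdict = rep$verdict,
      strt_start = rep$anchors$strt_start,
      hclp_start = rep$anchors$hclp_start,
      anchors = oc$anchors$status,
      lysine_upstream = oc$lysine_upstream$status,
      loop230 = oc$loop230$status,
      cterm_extension = oc$cterm_extension$status,
      helix13 = oc$helix13$status,
      evidence = paste(vapply(oc, function(o)
        sprintf("%s=%s", o$rule_id, o$evidence), character(1)),
        collapse = ";"),
      score = rep$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
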