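# Residues used for the helix-13 context: strongly helix-favoring under the
# Chou-Fasman table yet absent from every alternative set of the helix-13
# signature, so the signature occurs only where the generator implants it.
HELIX_CONTEXT_AA <- c("A", "E", "Q", "K")
# Extension residues for tail-lengthening ablations: helix-breaking and
# unable to form STRT/HCLP/SMG or any signature position.
NEUTRAL_TAIL_AA <- c("G", "S", "T")

#' Fixture specification for synthetic transcarbamylase-like sequences
#'
#' Describes one synthetic fixture: anchor positions mirror *E. faecalis*
#' PTC (STRT at 52, HCLP at 268, full-length model of 340 residues;
#' OTC-like fixtures default to 320 residues so the C-terminal tail is
#' about 20 residues shorter).
#'
#' @param seed Integer RNG seed.
#' @param length Sequence length (residues).
#' @param strt_pos,hclp_pos 1-based anchor start positions.
#' @param loop_variant `"ptc"` (230 loop, DVWYGLY) or `"otc"` (SMG loop,
#'   VSMG).
#' @param upstream_residue Residue placed two positions upstream of STRT
#'   (`"Q"` for PTC-like, `"K"` for OTC-like).
#' @param tail_signature Implant the helix-13 signature in a helix-favoring
#'   C-terminal context?
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, length = 340L, strt_pos = 52L,
                         hclp_pos = 268L, loop_variant = c("ptc", "otc"),
                         upstream_residue = "Q", tail_signature = TRUE) {
  loop_variant <- match.arg(loop_variant)
  stopifnot(strt_pos >= 3L,
            hclp_pos >= strt_pos + 190L, hclp_pos <= strt_pos + 240L,
            hclp_pos + 3L <= length,
            upstream_residue %in% AA_STANDARD)
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 strt_pos = as.integer(strt_pos),
                 hclp_pos = as.integer(hclp_pos),
                 loop_variant = loop_variant,
                 upstream_residue = upstream_residue,
                 tail_signature = tail_signature),
            class = "fixture_spec")
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

implant <- function(chars, pos, text) {
  sub <- strsplit(text, "")[[1]]
  chars[pos:(pos + length(sub) - 1L)] <- sub
  chars
}

count_substring <- function(s, sub) {
  length(gregexpr(sub, s, fixed = TRUE)[[1]][
    gregexpr(sub, s, fixed = TRUE)[[1]] > 0])
}

fixture_checks <- function(seqstr, spec, config) {
  rec <- seq_record("candidate", seqstr)
  if (count_substring(seqstr, config$strt) != 1L) return(FALSE)
  if (count_substring(seqstr, config$hclp) != 1L) return(FALSE)
  n_smg <- count_substring(seqstr, "SMG")
  anchors <- list(strt_start = spec$strt_pos, hclp_start = spec$hclp_pos)
  ptc_pat <- parse_pattern(config$loop_ptc, id = "loop_ptc")
  w <- loop_scan_window(anchors, config, length(ptc_pat$positions),
                        rec$length)
  n_loop_ptc <- nrow(scan_motif(rec, ptc_pat, w))
  h13 <- rule_helix13(rec, anchors, config)$status
  if (spec$loop_variant == "ptc") {
    if (n_smg != 0L || n_loop_ptc != 1L) return(FALSE)
  } else {
    if (n_smg != 1L || n_loop_ptc != 0L) return(FALSE)
  }
  if (spec$tail_signature) {
    if (h13 != "ptc_like") return(FALSE)
  } else {
    if (h13 == "ptc_like") return(FALSE)
  }
  TRUE
}

build_fixture <- function(spec, config) {
  attempt <- function(k) {
    chars <- sample(AA_STANDARD, spec$length, replace = TRUE)
    chars <- implant(chars, spec$strt_pos, config$strt)
    chars[spec$strt_pos - 2L] <- spec$upstream_residue
    chars <- implant(chars, spec$hclp_pos, config$hclp)
    if (spec$loop_variant == "ptc") {
      # DVWYGLY ending 35 residues before HCLP: YGLY starts hclp - 38
      chars <- implant(chars, spec$hclp_pos - 41L, "DVWYGLY")
    } else {
      # xSMG with the x residue 39 before HCLP
      chars <- implant(chars, spec$hclp_pos - 39L, "VSMG")
    }
    if (spec$tail_signature) {
      region_lo <- spec$length - 29L
      region_hi <- spec$length - 3L
      chars[region_lo:region_hi] <-
        sample(HELIX_CONTEXT_AA, region_hi - region_lo + 1L, replace = TRUE)
      chars <- implant(chars, spec$length - 10L, "LAAFL")
    }
    paste(chars, collapse = "")
  }
  for (k in seq_len(100L)) {
    seqstr <- attempt(k)
    if (fixture_checks(seqstr, spec, config)) return(seqstr)
  }
  stop("failed to generate an unambiguous fixture in 100 redraws",
       call. = FALSE)
}

make_fixture_record <- function(spec, class, config) {
  seqstr <- with_local_seed(spec$seed, build_fixture(spec, config))
  rec <- seq_record(sprintf("%s_like_seed%d", class, spec$seed), seqstr,
                    sprintf("synthetic %s-like fixture (seed %d)",
                            toupper(class), spec$seed))
  attr(rec, "fixture") <- c(spec[], list(class = class))
  rec
}

#' Generate a PTC-like synthetic sequence
#'
#' Seeded random background (uniform over the 20 standard residues) with
#' all five PTC signature traits implanted at *E. faecalis*-consistent
#' positions: STRT at `strt_pos`, a non-lysine (default Q) two residues
#' upstream, the 230 loop DVWYGLY with its YGLY core 38 residues before
#' HCLP, HCLP at `hclp_pos`, a C-terminal tail of >= 60 residues past HCLP
#' and the helix-13 signature (`LAAFL`) in a helix-favoring context near
#' the C terminus.  Backgrounds containing spurious anchors, SMG sequences
#' or extra 230-loop matches are rejected and redrawn (at most 100 times).
#'
#' @param spec A [fixture_spec()]; `seed` can be given directly.
#' @param config Classifier configuration, for the implanted patterns.
#' @return A `seq_record` carrying a `fixture` attribute (the implant map,
#'   needed by [ablate()]).
#' @export
generate_ptc_like <- function(spec = fixture_spec(),
                              config = classifier_config()) {
  if (is.numeric(spec)) spec <- fixture_spec(seed = spec)
  stopifnot(inherits(spec, "fixture_spec"))
  make_fixture_record(spec, "ptc", config)
}

#' Generate an OTC-like synthetic sequence
#'
#' As [generate_ptc_like()] but with the OTC traits: lysine two residues
#' upstream of STRT, the SMG loop (VSMG) in the 230-loop window, a short
#' C-terminal tail (default 320-residue length gives a 49-residue tail)
#' and no helix-13 signature.
#'
#' @inheritParams generate_ptc_like
#' @return A `seq_record` with a `fixture` attribute.
#' @export
generate_otc_like <- function(spec = NULL, config = classifier_config()) {
  if (is.null(spec)) spec <- fixture_spec(length = 320L, loop_variant = "otc",
                                          upstream_residue = "K",
                                          tail_signature = FALSE)
  if (is.numeric(spec)) spec <- fixture_spec(seed = spec, length = 320L,
                                             loop_variant = "otc",
                                             upstream_residue = "K",
                                             tail_signature = FALSE)
  stopifnot(inherits(spec, "fixture_spec"))
  make_fixture_record(spec, "otc", config)
}

#' Minimally edit a generated fixture to flip one signature rule
#'
#' Applies the smallest edit that flips the named rule to the opposite
#' family state, leaving the other rules untouched:
#' \describe{
#'   \item{anchors}{scrambles the STRT motif, so the sequence is no longer
#'     recognized as a transcarbamylase.}
#'   \item{lysine_upstream}{Q -> K (PTC-like records) or K -> Q (OTC-like).}
#'   \item{loop230}{YGLY -> VSMG, reproducing the engineered 230-loop
#'     swap, or the reverse on OTC-like records.}
#'   \item{cterm_extension}{on PTC-like records, truncation after residue
#'     317 (the C-terminal helix deletion construct); the helix-13
#'     signature block is re-implanted at the new C terminus so only the
#'     tail-length rule flips.  On OTC-like records the tail is extended
#'     past the PTC threshold with neutral helix-breaking residues.}
#'   \item{helix13}{replaces the implanted signature with helix-favoring
#'     residues that cannot match it.}
#' }
#' Ablations are idempotent: re-ablating an already-ablated record leaves
#' its classification unchanged.
#'
#' @param record A generator-produced `seq_record` (carries the implant map).
#' @param rule_id One of `"anchors"`, `"lysine_upstream"`, `"loop230"`,
#'   `"cterm_extension"`, `"helix13"`.
#' @param config Classifier configuration.
#' @return The edited `seq_record` (fixture attribute preserved, updated).
#' @export
ablate <- function(record, rule_id, config = classifier_config()) {
  fx <- attr(record, "fixture")
  if (is.null(fx))
    stop("record lacks a fixture implant map; only generator output can ",
         "be ablated", call. = FALSE)
  rule_id <- match.arg(rule_id, c("anchors", "lysine_upstream", "loop230",
                                  "cterm_extension", "helix13"))
  chars <- strsplit(record$residues, "")[[1]]
  to_otc <- fx$class == "ptc"
  if (rule_id == "anchors") {
    if (substr(record$residues, fx$strt_pos, fx$strt_pos + 3L) == "STRT")
      chars <- implant(chars, fx$strt_pos, "AGAG")
  } else if (rule_id == "lysine_upstream") {
    chars[fx$strt_pos - 2L] <- if (to_otc) "K" else "Q"
  } else if (rule_id == "loop230") {
    if (to_otc) {
      pos <- fx$hclp_pos - 38L
      if (substr(record$residues, pos, pos + 3L) != "VSMG")
        chars <- implant(chars, pos, "VSMG")
    } else {
      pos <- fx$hclp_pos - 39L
      if (substr(record$residues, pos, pos + 3L) == "VSMG")
        chars <- implant(chars, pos, "YGLY")
    }
  } else if (rule_id == "cterm_extension") {
    if (to_otc) {
      target <- 317L
      if (length(chars) > target) {
        chars <- chars[seq_len(target)]
        n <- length(chars)
        chars[(n - 29L):(n - 3L)] <- with_local_seed(
          fx$seed * 1000L + 7L,
          sample(HELIX_CONTEXT_AA, 27L, replace = TRUE))
        chars <- implant(chars, n - 10L, "LAAFL")
      }
    } else {
      target <- fx$hclp_pos + 3L + config$tail_ptc_min + 2L
      if (length(chars) < target) {
        anchors <- list(strt_start = fx$strt_pos, hclp_start = fx$hclp_pos)
        ok <- FALSE
        for (k in seq_len(100L)) {
          ext <- with_local_seed(
            fx$seed * 1000L + 13L + k,
            sample(NEUTRAL_TAIL_AA, target - length(chars), replace = TRUE))
          cand <- seq_record(record$id, paste(c(chars, ext), collapse = ""))
          if (rule_helix13(cand, anchors, config)$status != "ptc_like") {
            chars <- c(chars, ext); ok <- TRUE; break
          }
        }
        if (!ok) stop("failed to extend tail without creating a helix-13 ",
                      "signature", call. = FALSE)
      }
    }
  } else if (rule_id == "helix13") {
    sig_pos <- length(chars) - 10L
    if (substr(record$residues, sig_pos, sig_pos + 4L) == "LAAFL")
      chars <- implant(chars, sig_pos, "AEQKA")
  }
  out <- seq_record(paste0(record$id, "_ablate_", rule_id),
                    paste(chars, collapse = ""),
                    paste(record$description, "| ablated:", rule_id))
  fx$length <- out$length
  attr(out, "fixture") <- fx
  out
}
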