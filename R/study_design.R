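#' Default composition of a solicited-sound session script
#'
#' 46 isolated sounds — 18 coughs, 10 sneezes, 5 throat clears and 13
#' explosive words/numbers — each separated by at least 5 s of ambient
#' silence, plus one read-aloud text passage containing 2 embedded coughs,
#' for a total of 20 solicited coughs per session. Coughs make up
#' 18/46 = 39% of the isolated sounds.
#'
#' @return Named integer vector of isolated-sound counts plus
#'   `text_passage_coughs`.
#' @export
default_script_composition <- function() {
  c(cough = 18L, sneeze = 10L, throat_clear = 5L, word = 13L,
    text_passage_coughs = 2L)
}

#' Generate a solicited-sound session script
#'
#' Produces one script version: a deterministic random ordering (for the
#' given seed) of the isolated sounds, with the text passage inserted at a
#' random position, and a planned silent gap (>= 5 s) before every
#' instruction. The same seed always yields the same script; different
#' seeds permute the same sound multiset.
#'
#' @param version_seed Integer seed identifying the script version.
#' @param composition Named counts as in [default_script_composition()].
#' @param gap_range Range (seconds) the planned inter-sound gaps are drawn
#'   from; minimum must be >= 5.
#' @param passage_duration Duration in seconds of the read-aloud passage.
#' @return Data frame of class `script_spec` with columns `order`, `kind`,
#'   `gap_s` (silence preceding the instruction) and `duration_s`;
#'   attributes `version_seed`, `composition`, `n_coughs_total`.
#' @export
generate_script <- function(version_seed,
                            composition = default_script_composition(),
                            gap_range = c(5, 8), passage_duration = 60) {
  stopifnot(gap_range[1] >= 5, gap_range[2] >= gap_range[1],
            passage_duration > 0)
  iso <- composition[setdiff(names(composition), "text_passage_coughs")]
  if (any(iso < 0) || sum(iso) == 0L) {
    stop("invalid script composition", call. = FALSE)
  }
  kinds <- rep(names(iso), times = iso)
  with_preserved_seed({
    set.seed(as.integer(version_seed) %% .Machine$integer.max)
    kinds <- sample(kinds)
    pos <- sample.int(length(kinds) + 1L, 1L)
    kinds <- append(kinds, "text_passage", after = pos - 1L)
    gaps <- round(stats::runif(length(kinds), gap_range[1], gap_range[2]), 1)
  })
  out <- data.frame(
    order = seq_along(kinds), kind = kinds, gap_s = gaps,
    duration_s = ifelse(kinds == "text_passage", passage_duration, 0.5),
    stringsAsFactors = FALSE
  )
  attr(out, "version_seed") <- version_seed
  attr(out, "composition") <- composition
  attr(out, "n_coughs_total") <-
    unname(iso["cough"] + composition["text_passage_coughs"])
  class(out) <- c("script_spec", "data.frame")
  out
}

#' Fraction of isolated script sounds that are coughs
#'
#' @param script A `script_spec`.
#' @return Proportion of isolated (non-passage) sounds that are coughs.
#' @export
script_cough_fraction <- function(script) {
  iso <- script$kind[script$kind != "text_passage"]
  mean(iso == "cough")
}

#' Write a script to delimited text
#'
#' @param script A `script_spec`.
#' @param path Output path (tab-separated `order, kind, gap_s`).
#' @return `path`, invisibly.
#' @export
write_script <- function(script, path) {
  utils::write.table(script[c("order", "kind", "gap_s")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Buderer-style sample size for diagnostic accuracy
#'
#' Number of solicited sounds needed to estimate sensitivity and
#' specificity to a given precision. Each branch uses the normal
#' approximation `z^2 * p * (1 - p) / d^2` cases, inflated by the
#' prevalence of the target condition among sounds (coughs for
#' sensitivity, non-coughs for specificity) and by the anticipated dropout
#' rate; the result is the ceiling of the larger branch.
#'
#' @param sensitivity,specificity Target sensitivity and specificity, in
#'   (0,1).
#' @param precision Half-width `d` of the desired confidence interval, in
#'   (0,1).
#' @param prevalence Fraction of sounds that are coughs, in (0,1\].
#' @param dropout Anticipated dropout rate, in \[0,1).
#' @param confidence Confidence level determining `z` (default 0.95, i.e.
#'   z = 1.96).
#' @return Integer: required number of sounds (attribute `branches` gives
#'   the sensitivity- and specificity-branch requirements).
#' @export
buderer_sample_size <- function(sensitivity = 0.90, specificity = 0.85,
                                precision = 0.05, prevalence = 0.40,
                                dropout = 0.10, confidence = 0.95) {
  stopifnot(sensitivity > 0, sensitivity < 1, specificity > 0,
            specificity < 1, precision > 0, precision < 1,
            prevalence > 0, prevalence <= 1, dropout >= 0, dropout < 1,
            confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  # z for 95% is quoted as 1.96 in the standard formulation
  z <- round(z, 2)
  # a branch whose condition has zero prevalence is vacuous (nothing to
  # estimate it from): prevalence 1 drops the specificity branch
  branch <- function(p, prev) {
    if (prev <= 0) return(NA_real_)
    ceiling(z^2 * p * (1 - p) / precision^2 / prev / (1 - dropout))
  }
  n_se <- branch(sensitivity, prevalence)
  n_sp <- branch(specificity, 1 - prevalence)
  structure(as.integer(max(n_se, n_sp, na.rm = TRUE)),
            branches = c(sensitivity = n_se, specificity = n_sp))
}
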