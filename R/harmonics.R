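# Harmonic frequency-difference analysis. Overtones are estimated from
# sampled fundamentals (harmonic n of f1 is n * f1), differences are
# assayed at the four ratios typically associated with harmonic
# convergence (M1:F2, M2:F3, M3:F4, M3:F5), and categorised into the
# half-open bins [0,5), [5,10), [10,20), [20,50), [50,Inf) Hz. Differences
# below 5 Hz are harmonic convergence.

DIFF_LEVELS <- c("LT5", "LT10", "LT20", "LT50", "GT50")
MIXED_SCENARIOS <- c("S1_BOTH", "S2_EARLY_ONLY", "S3_LATE_ONLY", "NONE_GT50")

#' The four male:female harmonic ratios
#'
#' @return Data frame with columns `ratio` (`M1F2`, `M2F3`, `M3F4`,
#'   `M3F5`), `n_male`, `m_female`.
#' @export
harmonic_ratios <- function() {
  data.frame(ratio = c("M1F2", "M2F3", "M3F4", "M3F5"),
             n_male = c(1L, 2L, 3L, 3L),
             m_female = c(2L, 3L, 4L, 5L))
}

#' Harmonic overtone frequency
#'
#' @param f1 Fundamental frequency in Hz (> 0); vectorised.
#' @param n Harmonic index (integer >= 1; 1 is the fundamental).
#' @return `n * f1` in Hz.
#' @examples
#' harmonic(900, 2)  # 1800, the shared M2:F3 frequency with a 600 Hz female
#' @export
harmonic <- function(f1, n) {
  if (any(f1 <= 0)) stop("fundamental frequency must be positive")
  if (any(n < 1) || any(n != round(n))) stop("'n' must be an integer >= 1")
  n * f1
}

#' Harmonic frequency difference at one ratio
#'
#' @param male_f1,female_f1 Fundamentals in Hz (> 0); vectorised.
#' @param ratio One of `"M1F2"`, `"M2F3"`, `"M3F4"`, `"M3F5"`.
#' @return `|n_male * male_f1 - m_female * female_f1|` in Hz.
#' @examples
#' ratio_difference(900, 600, "M2F3")  # 0: harmony at 1800 Hz
#' @export
ratio_difference <- function(male_f1, female_f1, ratio) {
  hr <- harmonic_ratios()
  ratio <- match.arg(ratio, hr$ratio)
  r <- hr[hr$ratio == ratio, ]
  abs(harmonic(male_f1, r$n_male) - harmonic(female_f1, r$m_female))
}

#' Classify a harmonic frequency difference
#'
#' Half-open bins: `[0,5)` LT5 (harmonic convergence), `[5,10)` LT10,
#' `[10,20)` LT20, `[20,50)` LT50, `[50,Inf)` GT50. A difference of
#' exactly 5 Hz is therefore not convergence, and exactly 50 Hz falls in
#' GT50.
#'
#' @param diff Non-negative difference(s) in Hz.
#' @return Factor with levels `LT5`, `LT10`, `LT20`, `LT50`, `GT50`.
#' @export
classify_difference <- function(diff) {
  if (any(is.na(diff)) || any(diff < 0))
    stop("differences must be non-negative and non-missing")
  cut(diff, breaks = c(0, 5, 10, 20, 50, Inf), labels = DIFF_LEVELS,
      right = FALSE)
}

#' Best harmonic outcome across the four ratios
#'
#' Evaluates the harmonic difference at all four ratios and returns the
#' minimum-difference one; ties break in ratio order (M1F2, M2F3, M3F4,
#' M3F5).
#'
#' @param male_f1,female_f1 Fundamentals in Hz (> 0); vectorised.
#' @return Data frame `ratio`, `diff`, `category` (one row per input
#'   pair).
#' @examples
#' best_outcome(900, 600)     # M2F3, diff 0, convergence
#' @export
best_outcome <- function(male_f1, female_f1) {
  hr <- harmonic_ratios()
  diffs <- vapply(seq_len(nrow(hr)), function(k) {
    abs(hr$n_male[k] * male_f1 - hr$m_female[k] * female_f1)
  }, numeric(length(male_f1)))
  diffs <- matrix(diffs, ncol = nrow(hr))
  j <- max.col(-diffs, ties.method = "first")
  d <- diffs[cbind(seq_len(nrow(diffs)), j)]
  data.frame(ratio = hr$ratio[j], diff = d,
             category = classify_difference(d))
}

#' Collapse an interaction phase's sample points to one difference
#'
#' The phase-level difference is the minimum across the phase's three
#' sample points; in mixed-sex mode each point may use any of the four
#' ratios (the best outcome), in playback mode the ratio is fixed (M2:F3
#' against the known played female frequency).
#'
#' @param male_f0 Male fundamentals at the phase's sample points (Hz).
#' @param female_f0 Female fundamentals at the same points (mixed mode).
#' @param female_hz Known played female frequency (playback mode).
#' @param ratio Ratio used in playback mode (default `"M2F3"`).
#' @return `list(diff, category, ratio)` for the phase, or a GT50 result
#'   if no usable points exist.
#' @export
phase_outcome <- function(male_f0, female_f0 = NULL, female_hz = NULL,
                          ratio = "M2F3") {
  ok <- !is.na(male_f0)
  if (!is.null(female_f0)) ok <- ok & !is.na(female_f0)
  if (!any(ok))
    return(list(diff = Inf, category = factor("GT50", DIFF_LEVELS),
                ratio = NA_character_))
  if (is.null(female_hz)) {
    bo <- best_outcome(male_f0[ok], female_f0[ok])
    j <- which.min(bo$diff)
    list(diff = bo$diff[j], category = bo$category[j], ratio = bo$ratio[j])
  } else {
    d <- ratio_difference(male_f0[ok], female_hz, ratio)
    list(diff = min(d), category = classify_difference(min(d)),
         ratio = ratio)
  }
}

#' Mixed-sex interaction outcome scenario
#'
#' A phase "achieves" a harmonic difference when its category is not GT50.
#' Scenario 1: achieved both early and late; scenario 2: only early;
#' scenario 3: only late; otherwise the separate > 50 Hz outcome. Time
#' points with no interaction present (NA categories) also fall in the
#' > 50 Hz outcome.
#'
#' @param early_cat,late_cat Difference categories (factor or character);
#'   vectorised.
#' @return Factor with levels `S1_BOTH`, `S2_EARLY_ONLY`, `S3_LATE_ONLY`,
#'   `NONE_GT50`.
#' @export
scenario_mixed <- function(early_cat, late_cat) {
  ach <- function(x) {
    x <- as.character(x)
    !is.na(x) & x != "GT50"
  }
  e <- ach(early_cat); l <- ach(late_cat)
  out <- ifelse(e & l, "S1_BOTH",
         ifelse(e & !l, "S2_EARLY_ONLY",
         ifelse(!e & l, "S3_LATE_ONLY", "NONE_GT50")))
  factor(out, levels = MIXED_SCENARIOS)
}

#' Playback interaction outcome cell
#'
#' Playback interactions are scored against four references: the female
#' baseline tone and the female interaction tone, each both BEFORE and
#' DURING the male's interaction. The outcome is the 4-bit achievement
#' signature over those references (achieved = category not GT50),
#' a 16-cell lattice of which the observed scenarios are a subset.
#'
#' @param before_vs_base,before_vs_int,during_vs_base,during_vs_int
#'   Difference categories for the four references.
#' @return `list(signature, achieved, categories)`; `signature` is e.g.
#'   `"1001"` in the reference order above.
#' @export
scenario_playback <- function(before_vs_base, before_vs_int,
                              during_vs_base, during_vs_int) {
  cats <- list(before_vs_base = before_vs_base,
               before_vs_int = before_vs_int,
               during_vs_base = during_vs_base,
               during_vs_int = during_vs_int)
  ach <- vapply(cats, function(x) {
    x <- as.character(x)
    !is.na(x) && x != "GT50"
  }, logical(1))
  list(signature = paste0(as.integer(ach), collapse = ""),
       achieved = ach,
       categories = vapply(cats, as.character, character(1)))
}
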