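#' Pairwise cohort t-tests with FDR adjustment
#'
#' For each timepoint and scalar index, compares every cohort pair with an
#' unpaired two-sample t-test (Welch by default; set `pooled = TRUE` for
#' the equal-variance form). Slice records are first reduced to one mean
#' per animal so the animal, not the slice, is the experimental unit. All
#' raw p-values across the whole family (parameters x timepoints x pairs)
#' are adjusted together by [bh_adjust()].
#'
#' @param records slice-record tibble.
#' @param parameters index columns to test (default all seven).
#' @param region region whose records are tested (default `"distal"`).
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @param alpha significance level applied to the adjusted p-values.
#' @return tibble with one row per (parameter, week, cohort pair):
#'   `parameter`, `week`, `cohort_a`, `cohort_b`, `n_a`, `n_b`,
#'   `t`, `p`, `p_adjusted`, `significant`.
#' @export
pairwise_ttests <- function(records,
                            parameters = c("fa", "md", "ad", "rd", "mk", "ak", "rk"),
                            region = "distal", pooled = FALSE, alpha = 0.05) {
  per_animal <- records |>
    dplyr::filter(.data$region == !!region) |>
    dplyr::group_by(.data$animal, .data$cohort, .data$week) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(parameters), mean), .groups = "drop")

  rows <- list()
  for (wk in sort(unique(per_animal$week))) {
    at_wk <- dplyr::filter(per_animal, .data$week == wk)
    cohorts <- sort(unique(at_wk$cohort))
    if (length(cohorts) < 2) next
    pairs <- utils::combn(cohorts, 2, simplify = FALSE)
    for (pr in pairs) {
      xa <- dplyr::filter(at_wk, .data$cohort == pr[1])
      xb <- dplyr::filter(at_wk, .data$cohort == pr[2])
      if (nrow(xa) < 2 || nrow(xb) < 2) {
        message(sprintf("skipping %s vs %s at week %s: fewer than 2 animals in a cohort",
                        pr[1], pr[2], wk))
        next
      }
      for (par in parameters) {
        a <- xa[[par]]; b <- xb[[par]]
        if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
          tt <- list(statistic = c(t = 0), p.value = 1)
        } else {
          tt <- t.test(a, b, var.equal = pooled)
        }
        rows[[length(rows) + 1]] <- tibble(
          parameter = par, week = wk, cohort_a = pr[1], cohort_b = pr[2],
          n_a = nrow(xa), n_b = nrow(xb),
          t = unname(tt$statistic), p = tt$p.value)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$p_adjusted <- bh_adjust(out$p)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic false-discovery-rate adjustment: with p-values sorted ascending,
#' adjusted_(i) = min over j >= i of p_(j) * m / j, capped at 1 and mapped
#' back to the input order. Delegates to `stats::p.adjust(method = "BH")`,
#' which implements exactly this step-up rule.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= the input and <= 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y equal-length numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @param x_name,y_name labels carried into the result.
#' @return one-row tibble: `x`, `y`, `r`, `p`, `n`.
#' @export
pearson <- function(x, y, x_name = deparse(substitute(x)),
                    y_name = deparse(substitute(y))) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Pearson correlation needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: an input has zero variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  n_pairs <- length(x)
  tibble(x = x_name, y = y_name, r = unname(ct$estimate),
         p = ct$p.value, n = n_pairs)
}

#' Correlate per-nerve recovery probabilities with behavior
#'
#' Joins the per-nerve mean distal recovery probabilities of the injured
#' cohorts (crush and cut_repair) at the stated week with each animal's
#' behavioral scores at that week, and returns the Pearson correlations of
#' probability against SFI and against FF.
#'
#' @param nerves per-nerve summary from [classify_study()].
#' @param behavior behavioral tibble with `animal`, `week`, `sfi`, `ff`.
#' @param week endpoint week at which to correlate (default 12).
#' @return two-row tibble from [pearson()] (probability vs sfi, vs ff).
#' @export
correlate_probability_behavior <- function(nerves, behavior, week = 12) {
  nv <- dplyr::filter(nerves, .data$week == !!week, .data$assessable,
                      .data$cohort %in% c("crush", "cut_repair"))
  bh <- dplyr::filter(behavior, .data$week == !!week)
  joined <- dplyr::inner_join(nv, bh, by = c("animal", "cohort", "week"))
  if (nrow(joined) == 0) abort("no overlapping animals between assessments and behavior")
  dplyr::bind_rows(
    pearson(joined$mean_probability, joined$sfi, "probability", "sfi"),
    pearson(joined$mean_probability, joined$ff, "probability", "ff"))
}

#' Correlate scalar indices with axon density
#'
#' Reduces distal slice records to per-animal means (after the outlier
#' filter, which is always applied to this analysis), joins them with the
#' axon densities, and correlates each of RD, AD, RK, AK, RD/AD and FA
#' against density.
#'
#' @param records slice-record tibble.
#' @param histology tibble with `animal`, `axon_density`.
#' @param apply_filter apply [filter_outliers()] first (default TRUE).
#' @return tibble with one [pearson()] row per index.
#' @export
correlate_scalars_histology <- function(records, histology, apply_filter = TRUE) {
  recs <- dplyr::filter(records, .data$region == "distal")
  if (apply_filter) recs <- filter_outliers(recs)$kept
  per_animal <- recs |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(dplyr::across(c("rd", "ad", "rk", "ak", "fa"), mean),
                     .groups = "drop") |>
    dplyr::mutate(rd_ad = .data$rd / .data$ad)
  joined <- dplyr::inner_join(per_animal,
                              dplyr::select(histology, "animal", "axon_density"),
                              by = "animal")
  if (nrow(joined) < 3) abort("fewer than 3 animals with matched histology")
  purrr::map_dfr(c("rd", "ad", "rk", "ak", "rd_ad", "fa"), function(ix) {
    pearson(joined[[ix]], joined$axon_density, ix, "axon_density")
  })
}

#' Format p-values the way the study reports them
#'
#' Values below the floor are printed as `"< 1e-3"`; the exact value is
#' kept in the data, this is a display helper only.
#'
#' @param p numeric p-values.
#' @param floor display floor (default 1e-3).
#' @return character vector.
#' @export
format_pvalue <- function(p, floor = 1e-3) {
  ifelse(p < floor, paste0("< ", format(floor)), signif(p, 2))
}
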