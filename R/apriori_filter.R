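#' Knowledge-based a priori biomarker filter
#'
#' Selects features that behave like sleep-homeostat markers and rejects
#' clock-driven ones. A feature passes iff, in the training experiment:
#' (a) the fraction of participants with a significant linear trend
#' (raw p < `alpha`) whose slope sign matches the majority sign among the
#' significant participants is strictly greater than `min_linear_fraction`;
#' (b) the group-level linear fit is significant with that same sign; and
#' (c) the fraction of participants with a significant cosinor amplitude is
#' not strictly greater than `max_cyclic_fraction` (features rhythmic in more
#' than a quarter of participants are excluded as likely circadian-controlled,
#' a time-of-day confound for any deployed biomarker).
#'
#' @param individual_catalog individual-level `trend_catalog` on the training
#'   experiment's within view.
#' @param group_catalog group-level `trend_catalog` on the same view.
#' @param min_linear_fraction pass rule threshold (default 0.50, strict >).
#' @param max_cyclic_fraction exclusion threshold (default 0.25, strict >).
#' @param alpha per-test significance on raw p-values (default 0.05).
#' @param require_group_significant,require_direction_consensus toggles for
#'   rules (b) and the sign-consensus part of (a).
#' @return a `filter_report` data.frame: per feature, the driving fractions,
#'   majority direction, pass flag and failure reasons.
#' @export
apply_apriori_filter <- function(individual_catalog, group_catalog,
                                 min_linear_fraction = 0.50,
                                 max_cyclic_fraction = 0.25,
                                 alpha = 0.05,
                                 require_group_significant = TRUE,
                                 require_direction_consensus = TRUE) {
  stopifnot(inherits(individual_catalog, "trend_catalog"),
            inherits(group_catalog, "trend_catalog"))
  if (individual_catalog$level != "individual" || group_catalog$level != "group") {
    stop("need one individual-level and one group-level catalog")
  }
  ind <- individual_catalog$entries
  grp <- group_catalog$entries
  feats <- unique(ind$feature_id)
  if (!setequal(feats, grp$feature_id)) {
    stop("catalogs cover different feature universes")
  }
  n_part <- length(unique(ind$participant_id))
  grp <- grp[match(feats, grp$feature_id), ]
  rows <- lapply(feats, function(f) {
    e <- ind[ind$feature_id == f, ]
    sig_lin <- e$p_lin < alpha & e$slope != 0
    sig_cos <- e$p_cos < alpha
    frac_lin <- mean(sig_lin)
    frac_cos <- mean(sig_cos)
    maj_dir <- 0
    frac_consistent <- 0
    if (any(sig_lin)) {
      signs <- sign(e$slope[sig_lin])
      maj_dir <- ifelse(sum(signs > 0) >= sum(signs < 0), 1, -1)
      frac_consistent <- sum(sig_lin & sign(e$slope) == maj_dir) / n_part
    }
    data.frame(feature_id = f, frac_linear_significant = frac_lin,
               majority_direction = maj_dir,
               frac_consistent_direction = frac_consistent,
               frac_cosinor_significant = frac_cos,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$group_linear_p <- grp$p_lin
  rep$group_slope <- grp$slope
  lin_frac <- if (require_direction_consensus) {
    rep$frac_consistent_direction
  } else {
    rep$frac_linear_significant
  }
  ok_lin <- lin_frac > min_linear_fraction
  ok_grp <- !require_group_significant |
    (rep$group_linear_p < alpha & sign(rep$group_slope) == rep$majority_direction)
  ok_cyc <- !(rep$frac_cosinor_significant > max_cyclic_fraction)
  rep$passed <- ok_lin & ok_grp & ok_cyc
  rep$fail_reasons <- vapply(seq_len(nrow(rep)), function(i) {
    r <- character(0)
    if (!ok_lin[i]) {
      r <- c(r, if (rep$frac_linear_significant[i] > min_linear_fraction &&
                    require_direction_consensus)
        "no direction consensus" else "insufficient linear fraction")
    }
    if (!ok_grp[i]) r <- c(r, "group linear not significant/consistent")
    if (!ok_cyc[i]) r <- c(r, "cyclic in too many participants")
    paste(r, collapse = "; ")
  }, character(1))
  class(rep) <- c("filter_report", "data.frame")
  rep
}
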