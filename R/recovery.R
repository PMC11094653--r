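#' Pre/post-sleep block design for recovery contrasts
#'
#' Two designs compare candidate levels in 4-hour blocks before and after
#' the habitual sleep interval. `clock_matched` contrasts the same clock
#' times 24 h apart (sleep deprivation: 2--6 h vs 26--30 h since wake;
#' control: 2--6 h since wake on consecutive days). `evening_morning`
#' contrasts the evening before with the morning after sleep (sleep
#' deprivation: 12--16 h vs 26--30 h; control: day-2 12--16 h vs day-3
#' 2--6 h).
#'
#' @param design_kind `"clock_matched"` or `"evening_morning"`.
#' @return a `prepost_design` list with `sd_pre`, `sd_post` (TSW intervals)
#'   and `ctrl_pre`, `ctrl_post` (day + TSW interval).
#' @export
prepost_design <- function(design_kind = c("clock_matched", "evening_morning")) {
  design_kind <- match.arg(design_kind)
  if (design_kind == "clock_matched") {
    d <- list(sd_pre = c(2, 6), sd_post = c(26, 30),
              ctrl_pre = list(day = 2, tsw = c(2, 6)),
              ctrl_post = list(day = 3, tsw = c(2, 6)))
  } else {
    d <- list(sd_pre = c(12, 16), sd_post = c(26, 30),
              ctrl_pre = list(day = 2, tsw = c(12, 16)),
              ctrl_post = list(day = 3, tsw = c(2, 6)))
  }
  structure(c(list(design_kind = design_kind), d), class = "prepost_design")
}

in_block <- function(tsw, range) tsw >= range[1] & tsw <= range[2]

#' Stack candidate z-scores into a pre/post long table
#'
#' Restricts each protocol's within-participant z-scored table to the
#' design's pre and post blocks for the candidate features and stacks the
#' result in long format, ready for the mixed-model contrast.
#'
#' @param tables named list of within-view tables (`data_view` or z-scored
#'   `feature_table`), e.g.
#'   `list(sleep_dep_exp1 = ..., sleep_dep_exp2 = ..., matched_control = ...)`.
#' @param design a [prepost_design()].
#' @param candidates feature ids present in every table.
#' @return data.frame: `value_z`, `period` (factor pre/post), `participant`,
#'   `protocol`, `metabolite`, `tsw_hours`.
#' @export
build_pre_post <- function(tables, design, candidates) {
  stopifnot(inherits(design, "prepost_design"))
  if (length(candidates) == 0) stop("candidate list is empty")
  rows <- lapply(names(tables), function(nm) {
    tab <- tables[[nm]]
    if (inherits(tab, "data_view")) tab <- tab$table
    stopifnot(inherits(tab, "feature_table"))
    missing_feats <- setdiff(candidates, tab$feature_meta$feature_id)
    if (length(missing_feats)) {
      stop("candidates absent from table '", nm, "': ",
           paste(missing_feats, collapse = ", "))
    }
    sm <- tab$sample_meta
    is_ctrl <- sm$protocol_kind[1] == "matched_control"
    if (is_ctrl) {
      pre <- sm$day_index == design$ctrl_pre$day &
        in_block(sm$tsw_hours, design$ctrl_pre$tsw)
      post <- sm$day_index == design$ctrl_post$day &
        in_block(sm$tsw_hours, design$ctrl_post$tsw)
    } else {
      pre <- in_block(sm$tsw_hours, design$sd_pre)
      post <- in_block(sm$tsw_hours, design$sd_post)
    }
    if (!any(pre) || !any(post)) {
      stop("empty ", if (!any(pre)) "pre" else "post", " block for protocol '",
           nm, "'")
    }
    idx <- which(pre | post)
    period <- ifelse(pre[idx], "pre", "post")
    do.call(rbind, lapply(candidates, function(f) {
      data.frame(value_z = tab$intensities[idx, f],
                 period = period,
                 participant = as.character(sm$participant_id[idx]),
                 protocol = nm, metabolite = f,
                 tsw_hours = sm$tsw_hours[idx],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$period <- factor(out$period, levels = c("pre", "post"))
  rownames(out) <- NULL
  out
}

#' Mixed-model pre/post contrasts per metabolite and protocol
#'
#' For every (metabolite, protocol) pair fits
#' `value_z ~ period + (1 | participant)` and reports the post-minus-pre
#' estimate with Satterthwaite degrees of freedom and t ratio. P-values are
#' FDR-adjusted across all tests within the design; the trend is
#' `increasing`/`decreasing` by the estimate's sign when the adjusted p is
#' below `alpha`, otherwise `not_significant`. A singular or failed fit
#' falls back to a paired t-test on participant means (logged via message).
#'
#' @param stacked long table from [build_pre_post()].
#' @param alpha significance level on the FDR-adjusted p (default 0.05).
#' @return a `recovery_result` data.frame: metabolite, protocol, estimate,
#'   df, t_ratio, p_value, p_fdr, trend.
#' @export
fit_prepost_model <- function(stacked, alpha = 0.05) {
  req <- c("value_z", "period", "participant", "protocol", "metabolite")
  stopifnot(all(req %in% names(stacked)))
  stacked$period <- factor(as.character(stacked$period),
                           levels = c("pre", "post"))
  if (anyNA(stacked$period)) stop("period must be 'pre' or 'post'")
  cells <- unique(stacked[, c("metabolite", "protocol")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- stacked[stacked$metabolite == cells$metabolite[i] &
                   stacked$protocol == cells$protocol[i], ]
    res <- tryCatch({
      m <- suppressMessages(lmerTest::lmer(
        value_z ~ period + (1 | participant), data = d))
      co <- stats::coef(summary(m))["periodpost", ]
      list(estimate = co[["Estimate"]], df = co[["df"]],
           t_ratio = co[["t value"]], p = co[["Pr(>|t|)"]])
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$p)) {
      message("mixed model failed for ", cells$metabolite[i], " / ",
              cells$protocol[i], "; using paired t-test on participant means")
      pm <- stats::aggregate(value_z ~ participant + period, d, mean)
      wide <- stats::reshape(pm, idvar = "participant", timevar = "period",
                             direction = "wide")
      diffs <- wide$value_z.post - wide$value_z.pre
      tt <- tryCatch(stats::t.test(diffs), error = function(e) NULL)
      if (is.null(tt) || !is.finite(tt$p.value)) {
        # zero-variance differences: no evidence of change
        res <- list(estimate = mean(diffs), df = length(diffs) - 1,
                    t_ratio = 0, p = 1)
      } else {
        res <- list(estimate = unname(tt$estimate), df = unname(tt$parameter),
                    t_ratio = unname(tt$statistic), p = tt$p.value)
      }
    }
    data.frame(metabolite = cells$metabolite[i], protocol = cells$protocol[i],
               estimate = res$estimate, df = res$df, t_ratio = res$t_ratio,
               p_value = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p_value, "BH")
  out$trend <- ifelse(out$p_fdr >= alpha, "not_significant",
                      ifelse(out$estimate > 0, "increasing", "decreasing"))
  class(out) <- c("recovery_result", "data.frame")
  out
}

#' Does meal schedule alter a candidate's trend with time awake?
#'
#' Compares a well-rested day sampled under the two feeding regimes (hourly
#' identical snacks during the constant routine vs three meals plus snacks
#' in the matched control) with the mixed model
#' `value_z ~ tsw * protocol + (1 | participant)`. A large interaction
#' p-value indicates the candidate's trend with time since wake does not
#' depend on the protocol/diet.
#'
#' @param control_day,sleepdep_day `feature_table`s (z-scored across the
#'   compared day) holding the control and sleep-deprivation WR-day samples.
#' @param candidates feature ids.
#' @return data.frame: metabolite, interaction estimate, p-value.
#' @export
meal_timing_comparison <- function(control_day, sleepdep_day, candidates) {
  if (inherits(control_day, "data_view")) control_day <- control_day$table
  if (inherits(sleepdep_day, "data_view")) sleepdep_day <- sleepdep_day$table
  rows <- lapply(candidates, function(f) {
    d <- rbind(
      data.frame(value_z = control_day$intensities[, f],
                 tsw = control_day$sample_meta$tsw_hours,
                 participant = as.character(control_day$sample_meta$participant_id),
                 protocol = "matched_control", stringsAsFactors = FALSE),
      data.frame(value_z = sleepdep_day$intensities[, f],
                 tsw = sleepdep_day$sample_meta$tsw_hours,
                 participant = as.character(sleepdep_day$sample_meta$participant_id),
                 protocol = "sleep_deprivation", stringsAsFactors = FALSE)
    )
    if (length(unique(d$protocol)) < 2) {
      return(data.frame(metabolite = f, interaction_estimate = 0,
                        p_interaction = 1, stringsAsFactors = FALSE))
    }
    d$protocol <- factor(d$protocol)
    res <- tryCatch({
      m <- suppressMessages(lmerTest::lmer(
        value_z ~ tsw * protocol + (1 | participant), data = d))
      co <- stats::coef(summary(m))
      ix <- grep(":", rownames(co))
      list(est = co[ix, "Estimate"], p = co[ix, "Pr(>|t|)"])
    }, error = function(e) {
      m <- stats::lm(value_z ~ tsw * protocol, data = d)
      co <- stats::coef(summary(m))
      ix <- grep(":", rownames(co))
      list(est = co[ix, "Estimate"], p = co[ix, "Pr(>|t|)"])
    })
    data.frame(metabolite = f, interaction_estimate = res$est,
               p_interaction = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
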