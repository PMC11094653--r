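# Shared fixtures, built in code.

# A small raw feature table with hand-controlled values.
tiny_table <- function(values, tsw = NULL, participants = NULL) {
  m <- as.matrix(values)
  n <- nrow(m)
  if (is.null(tsw)) tsw <- seq(2, by = 2, length.out = n)
  if (is.null(participants)) participants <- rep("P01", n)
  feature_table(
    m,
    data.frame(sample_id = paste0("s", seq_len(n)),
               participant_id = participants, experiment_id = "expT",
               tsw_hours = tsw, day_index = 1L,
               protocol_kind = "sleep_deprivation"),
    data.frame(feature_id = colnames(m) %||% paste0("F", seq_len(ncol(m))))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default-condition synthetic study: one panel shared by training, test and
# matched-control experiments (the study layout every pipeline test assumes).
synth_study <- function(class_counts = c(linear = 20, circadian = 50,
                                         mixed = 30, null = 900),
                        panel_seed = 42, seeds = c(101, 202, 303)) {
  panel <- make_feature_panel(class_counts, seed = panel_seed)
  e1 <- generate_sleep_dep_experiment(
    panel, protocol_spec("sleep_deprivation", 12,
                         missing_sample_rate = 10 / 228, seed = seeds[1]),
    "exp1")
  e2 <- generate_sleep_dep_experiment(
    panel, protocol_spec("sleep_deprivation", 11,
                         missing_sample_rate = 11 / 209, seed = seeds[2]),
    "exp2", scale_factor = 1.15)
  ctrl <- generate_matched_control(
    panel, protocol_spec("matched_control", 5, seed = seeds[3]), "ctrl")
  list(panel = panel, exp1 = e1, exp2 = e2, ctrl = ctrl)
}

# The five strongest planted homeostatic features (by relative slope): the
# candidates a perfect selection stage would return.
planted_candidates <- function(panel, n = 5) {
  lin <- panel[panel$true_class == "linear", ]
  lin$feature_id[order(-abs(lin$slope) / lin$baseline)][seq_len(n)]
}

# Predictor matrix with 5 individually-weak, jointly-strong informative
# variables, 5 noisy correlates of them, and 10 pure-noise variables.
planted_selection_problem <- function(n = 200, seed = 7) {
  set.seed(seed)
  S <- matrix(rnorm(n * 5), n, 5)
  X <- cbind(S,
             S + matrix(rnorm(n * 5, 0, 1.5), n, 5),
             matrix(rnorm(n * 10), n, 10))
  colnames(X) <- c(paste0("info", 1:5), paste0("cor", 1:5), paste0("noise", 1:10))
  y <- factor(ifelse(rowSums(S) + rnorm(n, 0, 0.5) > 0, "SD", "WR"),
              levels = c("WR", "SD"))
  list(X = as.data.frame(X), y = y, informative = paste0("info", 1:5))
}
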