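# Fixtures built in code.

# The pilot panel's printed descriptive table: 17 judges, percent scale.
pilot_summary <- function() {
  panel_summary(n = 17,
                mean_L = 62.65, se_L = 5.609, sd_L = 23.12,
                mean_H = 65.35, se_H = 3.193, sd_H = 13.16,
                mean_suggested = 60.47, se_suggested = 2.756,
                sd_suggested = 11.36,
                label = "pilot exam")
}

make_panel <- function(L, H, suggested = NULL, ...) {
  df <- data.frame(judge_id = paste0("j", seq_along(L)), L = L, H = H)
  if (!is.null(suggested)) df$suggested <- suggested
  judge_panel(df, ...)
}

random_panel <- function(n, seed) {
  set.seed(seed)
  L <- runif(n, 30, 70)
  make_panel(L = L, H = L + runif(n, 2, 25))
}
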