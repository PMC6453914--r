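# Independent oracles used to cross-check the implementation.

# Scalar reimplementation of the mode definitions straight from their verbal
# form, on the log scale (deliberately different code path from the
# package's ratio-based classifier).
oracle_classify <- function(p_cor, p_wl, h, threshold = 1.25) {
  similar <- function(x, y) {
    if (x == 0 && y == 0) return(TRUE)
    if (x == 0 || y == 0) return(FALSE)
    abs(log(x) - log(y)) < log(threshold)
  }
  if (p_cor == 0 && p_wl == 0 && h == 0) return("unclassified_zero")
  sim_c <- similar(h, p_cor)
  sim_w <- similar(h, p_wl)
  if (sim_c && sim_w) return("conserved")
  if (sim_c) return("cor_dominant")
  if (sim_w) return("wl_dominant")
  if (h > min(p_cor, p_wl) && h < max(p_cor, p_wl)) return("additive")
  if (h > max(p_cor, p_wl)) return("over_dominant")
  "under_dominant"
}

# Closed-form simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Brute-force Venn region counts by per-gene membership enumeration.
oracle_venn <- function(gene_sets) {
  universe <- unique(unlist(gene_sets))
  sig <- vapply(universe, function(g) {
    paste(names(gene_sets)[vapply(gene_sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(sig)
}

# Small engineered expression profile: one gene per inheritance mode for
# every group, plus an all-zero gene in the CL units only.
toy_profile <- function() {
  vals <- tibble::tibble(
    gene_id = paste0("t", 1:7),
    p_cor = c(1.0, 2.0, 2.0, 2.0, 2.0, 2.0, 0),
    p_wl  = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.5, 0),
    h     = c(1.0, 1.5, 2.1, 1.05, 3.0, 1.0, 0)
  )
  out <- tibble::tibble(gene_id = vals$gene_id)
  for (u in c("CC_M", "CC_F")) out[[u]] <- vals$p_cor
  for (u in c("CW_M", "CW_F")) out[[u]] <- vals$p_wl
  for (u in c("CL_M", "CL_F")) out[[u]] <- vals$h
  # LC units: make gene t7 expressed there so the zero rule is per-group
  # (silent in the CL-based groups, classifiable in the LC-based ones)
  for (u in c("LC_M", "LC_F")) out[[u]] <- replace(vals$h, 7, 1.0)
  out
}
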