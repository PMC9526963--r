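# Shared fixtures: all constructed in code at test time.

# Large-effect reference design: a3 = b3 = 0.59, c' = 0.39, ICCs (.2, .1, .2).
large_effect_design <- function(n3 = 20, n2 = 5, n1 = 3, icc_y2 = 0.1) {
  design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39, b2 = 0.39,
              icc_m3 = 0.2, icc_y2 = icc_y2, icc_y3 = 0.2,
              n3 = n3, n2 = n2, n1 = n1)
}

# A null design: both indirect-effect paths zero.
null_design <- function(n3 = 10, n2 = 5, n1 = 3) {
  d <- design_grid(a3 = 0.39, b3 = 0.39, c3p = 0.14,
                   icc_m3 = 0.2, icc_y2 = 0.1, icc_y3 = 0.2,
                   n3 = n3, n2 = n2, n1 = n1)
  d$a3 <- 0
  d$b3 <- 0
  d
}

# Hand-built population parameter row (bypasses the standardized mapping) so
# degenerate variance structures can be simulated directly.
raw_params <- function(a_raw = 0, b3_raw = 0, b2_raw = 0, c_raw = 0,
                       var_mB_resid = 0, var_mW = 0, var_yB_resid = 0,
                       var_y2_resid = 0, var_y1 = 0,
                       n3 = 10, n2 = 5, n1 = 3) {
  tibble::tibble(a_raw = a_raw, b3_raw = b3_raw, b2_raw = b2_raw,
                 c_raw = c_raw, var_mB_resid = var_mB_resid, var_mW = var_mW,
                 var_yB_resid = var_yB_resid, var_y2_resid = var_y2_resid,
                 var_y1 = var_y1, n3 = n3, n2 = n2, n1 = n1)
}

# The attenuated large-sample limit of the manifest between-cluster slope:
# regressing cluster-mean Y on cluster-mean M mixes the latent level-3 slope
# with the within-cluster slope in proportion to their shares of the
# cluster-mean variance.
attenuated_b3 <- function(b3_raw, b2_raw, var_mB_resid, var_mW, n2) {
  (b3_raw * var_mB_resid + b2_raw * var_mW / n2) / (var_mB_resid + var_mW / n2)
}
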