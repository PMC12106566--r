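# shared fixtures, all built in code

model_predictors <- c("np_t2", "subject_height", "midsag_area", "volume")

# the frozen coefficient table, typed independently of the packaged JSON so
# encoding tests compare computation against these values
frozen_table <- list(
  "L1-L2" = c(intercept = 142.3, t2 = -0.3950, height = -1.050,
              area = -0.04852, volume = 0.002585, rmse = 10.4),
  "L2-L3" = c(intercept = 140.2, t2 = -0.3879, height = -0.8855,
              area = -0.07195, volume = 0.002040, rmse = 10.1),
  "L3-L4" = c(intercept = 163.4, t2 = -0.3645, height = -1.263,
              area = -0.1058, volume = 0.002737, rmse = 8.8),
  "L4-L5" = c(intercept = 156.3, t2 = -0.3319, height = -1.297,
              area = -0.09644, volume = 0.002920, rmse = 11.3),
  "L5-S1" = c(intercept = 165.8, t2 = -0.2701, height = -1.498,
              area = -0.1399, volume = 0.004336, rmse = 13.8))

# evaluate the packaged model through the scoring path at given inputs
score_at <- function(level, t2 = 0, ht = 0, area = 0, vol = 0) {
  p <- disc_predictors(level, t2, ht, area, vol, test_mode = TRUE)
  as.numeric(effective_age(p))
}

# a 3D box mask: true inside [a1:a2, s1:s2, l1:l2]
box_mask <- function(dims, a = c(1, dims[1]), s = c(1, dims[2]),
                     l = c(1, dims[3]), spacing = c(1, 1, 1),
                     midsag = ceiling(dims[3] / 2)) {
  arr <- array(FALSE, dim = dims)
  arr[a[1]:a[2], s[1]:s[2], l[1]:l[2]] <- TRUE
  segmentation_mask(arr, spacing = spacing, midsag_slice = midsag)
}

# rectangular interspace fiducials: width w, anterior half-gap ha,
# posterior half-gap hp, centred at `centre`
rect_fiducials <- function(w, ha, hp = ha, centre = c(0, 0)) {
  fiducial_set(centre + c(w / 2, ha), centre + c(-w / 2, hp),
               centre + c(w / 2, -ha), centre + c(-w / 2, -hp))
}

# uniform-value multi-echo stack
uniform_stack <- function(nr, nc, value, echo_times = default_echo_times()) {
  st <- array(value, dim = c(nr, nc, length(echo_times)))
  attr(st, "echo_times") <- echo_times
  st
}

# small cohort for fast model-development tests
quick_cohort <- function(seed, ...) {
  suppressMessages(generate_cohort(cohort_spec(seed = seed, ...)))
}

# independent normal-equations OLS oracle
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  solve(crossprod(Xi), crossprod(Xi, y))[, 1]
}
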