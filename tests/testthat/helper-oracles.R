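# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (brute force, quadrature, enumeration): they are the
# reference the fast implementations are checked against.

# adaptive-quadrature ellipse perimeter: 4a * int_0^{pi/2} sqrt(1-m sin^2 t) dt
quad_circumference <- function(a, b) {
  m <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(pmax(1 - m * sin(t)^2, 0)),
                           0, pi / 2, rel.tol = 1e-13,
                           subdivisions = 400L)$value
}

# parametric points on an ellipse in (row, col) convention
ellipse_points <- function(cr, cc, a, b, theta_deg, n = 100, jitter_sd = 0) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- theta_deg * pi / 180
  row <- cr + a * cos(phi) * sin(th) + b * sin(phi) * cos(th)
  col <- cc + a * cos(phi) * cos(th) - b * sin(phi) * sin(th)
  if (jitter_sd > 0) {
    row <- row + stats::rnorm(n, 0, jitter_sd)
    col <- col + stats::rnorm(n, 0, jitter_sd)
  }
  cbind(row = row, col = col)
}

# random connected-ish blob: union of random discs on a small grid
random_blob <- function(seed, dims = c(60, 60), n_discs = 4) {
  set.seed(seed)
  g <- matrix(FALSE, dims[1], dims[2])
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  for (i in seq_len(n_discs)) {
    r0 <- runif(1, 15, dims[1] - 15); c0 <- runif(1, 15, dims[2] - 15)
    rad <- runif(1, 3, 10)
    g <- g | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
  }
  g
}

# brute-force vertical bounding-box depth over the occupied set
brute_depth <- function(grid) {
  occ <- which(grid, arr.ind = TRUE)
  max(occ[, 1]) - min(occ[, 1])
}

# exact two-sided signed-rank p by enumeration over all 2^n sign
# assignments of the ranks of |d| (midranks for ties)
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# one randomized phantom case measured end-to-end; returns relative errors
measure_phantom_case <- function(kind, seed) {
  cs <- random_phantom_spec(kind, seed)
  if (kind == "amniotic") {
    ph <- generate_af_loop(cs$spec)
    be <- phantom_backend(ph$truth, cs$degrade_px, cs$degrade_mode)
    sm <- measure_sdp_loop(ph$loop, be)
    # brute-force maximum over every planted pocket in every frame
    brute <- -Inf
    for (fr in ph$loop$frames) {
      for (inst in segment_frame(fr, "amniotic", be)) {
        occ <- which(inst$mask$grid, arr.ind = TRUE)
        brute <- max(brute, (max(occ[, 1]) - min(occ[, 1])) *
                       fr$row_spacing_cm)
      }
    }
    list(kind = kind,
         rel_err = c(SDP = abs(sm$depth_cm / ph$truth$analytic$SDP_cm - 1)),
         sdp_equals_brute = isTRUE(all.equal(sm$depth_cm, brute)),
         afv = sm$afv_category)
  } else {
    ph <- generate_biometry_loop(cs$spec)
    be <- phantom_backend(ph$truth, cs$degrade_px, cs$degrade_mode)
    pm <- measure_biometry_loop(ph$loop, be)
    tr <- ph$truth$analytic
    rel <- c()
    if (!is.null(pm$HC_cm)) rel["HC"] <- abs(pm$HC_cm / tr$HC_cm - 1)
    if (!is.null(pm$BPD_cm)) rel["BPD"] <- abs(pm$BPD_cm / tr$BPD_cm - 1)
    if (!is.null(pm$AC_cm)) rel["AC"] <- abs(pm$AC_cm / tr$AC_cm - 1)
    if (!is.null(pm$FL_cm)) rel["FL"] <- abs(pm$FL_cm / tr$FL_cm - 1)
    list(kind = kind, rel_err = rel,
         selected_best = pm$frame_index == ph$truth$best_frame)
  }
}
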