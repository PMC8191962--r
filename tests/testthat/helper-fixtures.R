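# Programmatic fixtures and independent oracles used across the suite.

# triangular strain pulse: 0 -> -depth at t_apex -> 0 at t_end, then flat 0
triangular_trace <- function(depth = 20, t_apex = 0.3, t_end = 0.6,
                             cycle = 0.8, rate = 100, segment_id = "BS") {
  t <- seq(0, cycle, by = 1 / rate)
  s <- ifelse(t <= t_apex, -depth * t / t_apex,
              ifelse(t <= t_end, -depth * (t_end - t) / (t_end - t_apex), 0))
  strain_trace(segment_id, t, s)
}

# closed-form value of the triangular pulse at arbitrary times
triangular_value <- function(t, depth = 20, t_apex = 0.3, t_end = 0.6) {
  ifelse(t <= t_apex, -depth * t / t_apex,
         ifelse(t <= t_end, -depth * (t_end - t) / (t_end - t_apex), 0))
}

# noiseless raised-cosine lobe value (negative systolic lobe only)
raised_cosine_value <- function(t, amplitude, t_peak, width) {
  x <- (t - t_peak) / width
  ifelse(abs(x) <= 0.5, -amplitude * 0.5 * (1 + cos(2 * pi * x)), 0)
}

# independent fine-grid oracle for the dead-zone-masked integral of an
# analytic curve: Riemann-midpoint at 200 kHz
masked_integral_oracle <- function(curve_fun, t_end, dead_zone = 5,
                                   dt = 5e-6) {
  t <- seq(dt / 2, t_end - dt / 2, by = dt)
  s <- curve_fun(t)
  sum(ifelse(s < -dead_zone, -s, 0)) * dt
}

# a random noiseless view recording with valid segment params
random_view <- function(view = "4ch", cycle = 0.8, rate = 100,
                        t_avc = 0.38) {
  segs <- view_segments(view)
  traces <- lapply(segs, function(sg) {
    amp <- runif(1, 6, 24)
    tp <- runif(1, 0.22, 0.45)
    wd <- runif(1, 0.2, min(2 * tp, 2 * (cycle - tp)))
    make_segment_curve(segment_params(amp, tp, wd,
                                      rebound_fraction = runif(1, 0, 0.4)),
                       cycle, rate, segment_id = sg)
  })
  view_recording(view, traces, t_avc)
}

# small fully synthetic patient (three noiseless views)
tiny_patient <- function(id = "P1", esv0 = 200, esv1 = 150) {
  views <- list("4ch" = random_view("4ch"),
                "3ch" = random_view("3ch", t_avc = 0.37),
                "2ch" = random_view("2ch", t_avc = 0.36))
  patient_record(id, views, qrs_duration = 160, lvef = 30,
                 esv_baseline = esv0, esv_followup = esv1)
}

# naive ReliefF: direct neighbor scan, mirrors the documented update rule
relief_naive <- function(X, y, k) {
  X <- as.matrix(X)
  rng <- apply(X, 2, function(x) diff(range(x)))
  rng[rng == 0] <- Inf
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  n <- nrow(Xs)
  w <- numeric(ncol(Xs))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(Xs) - Xs[i, ])^2))
    acc <- function(idx) {
      if (!length(idx)) return(0)
      nb <- idx[order(d[idx], idx)][seq_len(min(k, length(idx)))]
      colMeans(abs(Xs[nb, , drop = FALSE] -
                     matrix(Xs[i, ], length(nb), ncol(Xs), byrow = TRUE)))
    }
    same <- setdiff(which(y == y[i]), i)
    w <- w + acc(which(y != y[i])) - acc(same)
  }
  w / n
}

# naive CWF: recompute eligibility and mean ranks from the top lists
cwf_naive <- function(rankings, top_k = 20, min_methods = 3) {
  tops <- lapply(rankings, function(r) head(r$feature, top_k))
  univ <- sort(unique(unlist(tops)))
  rows <- lapply(univ, function(f) {
    pos <- vapply(tops, function(tl) match(f, tl), numeric(1))
    if (sum(!is.na(pos)) < min_methods) return(NULL)
    data.frame(feature = f, score = mean(pos, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(feature = character(0),
                                      score = numeric(0)))
  out <- out[order(out$score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random permutation ranking over a fixed universe
random_ranking <- function(universe, method = "m") {
  perm <- sample(universe)
  importance_ranking(method, perm, seq(length(perm), 1))
}
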