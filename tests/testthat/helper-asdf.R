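# Pure-R mirror of the compiled triplet scan, assembled from the exported
# reference operations plus the same 3D vector fit; used to cross-check
# the compiled path on small inputs.
cross3_h <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

scan_triplets_r <- function(points, indices, lmin, lmax, n_bins = 1024L,
                            fit_tol = 0.15, min_fit = 7L) {
  opt <- asdf_options(direct_length_min = lmin, direct_length_max = lmax,
                      n_bins = n_bins, fit_tolerance = fit_tol,
                      min_fit_points = min_fit)
  out <- NULL
  for (r in seq_len(nrow(indices))) {
    p1 <- points[indices[r, 1], ]; p2 <- points[indices[r, 2], ]
    p3 <- points[indices[r, 3], ]
    nh <- cross3_h(p2 - p1, p3 - p1)
    nn <- sqrt(sum(nh^2))
    if (nn < 1e-12) next
    nh <- nh / nn
    d <- project_distances(points, nh)
    if (max(d) - min(d) <= 0) next
    h <- periodicity_histogram(d, n_bins)
    L0 <- fft_candidate_length(h$histogram, h$range, opt)
    if (is.null(L0)) next
    rf <- refine_repeat(d, L0, opt)
    if (is.null(rf) || !rf$accepted) next
    tvec <- nh * rf$length
    for (it in 1:5) {
      md <- as.numeric(points %*% tvec)
      sel <- abs(md - round(md)) <= fit_tol
      if (sum(sel) < 3) break
      Q <- points[sel, , drop = FALSE]
      m <- round(md[sel])
      tnew <- tryCatch(as.numeric(solve(crossprod(Q), crossprod(Q, m))),
                       error = function(e) NULL)
      if (is.null(tnew) || sqrt(sum(tnew^2)) < 1e-9) break
      conv <- sqrt(sum((tnew - tvec)^2)) <= 1e-10 * sqrt(sum(tvec^2))
      tvec <- tnew
      if (conv) break
    }
    L <- sqrt(sum(tvec^2))
    if (L < lmin || L > lmax) next
    md <- as.numeric(points %*% tvec)
    m <- round(md)
    nfit <- sum(m != 0 & abs(md - m) <= fit_tol)
    if (nfit < min_fit) next
    out <- rbind(out, c(tvec, L, nfit))
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 5)
  colnames(out) <- c("tx", "ty", "tz", "L", "n_fit")
  out
}
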