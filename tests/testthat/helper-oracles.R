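# Independent brute-force oracles used across the suite. These stay
# deliberately separate from the package's own code paths: statistics
# come from stats::wilcox.test / stats::kruskal.test and the labelings
# are enumerated with utils::combn directly.

# Exact two-sided Mann-Whitney p by full enumeration of labelings.
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  mu <- na * length(b) / 2
  u_of <- function(x, y) unname(suppressWarnings(
    wilcox.test(x, y, exact = FALSE)$statistic))
  u_obs <- u_of(a, b)
  subsets <- combn(n, na, simplify = FALSE)
  us <- vapply(subsets, function(idx) u_of(pooled[idx], pooled[-idx]),
               numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exact Kruskal-Wallis p by enumeration of all distinct assignments of
# the pooled values to groups of the observed sizes (2 or 3 groups).
oracle_kw_p <- function(groups) {
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  h_of <- function(gs) unname(suppressWarnings(
    kruskal.test(gs)$statistic))
  h_obs <- h_of(groups)
  hs <- numeric(0)
  if (length(sizes) == 2L) {
    for (idx in combn(n, sizes[1], simplify = FALSE))
      hs <- c(hs, h_of(list(pooled[idx], pooled[-idx])))
  } else if (length(sizes) == 3L) {
    for (i1 in combn(n, sizes[1], simplify = FALSE)) {
      rest <- setdiff(seq_len(n), i1)
      for (i2 in combn(length(rest), sizes[2], simplify = FALSE))
        hs <- c(hs, h_of(list(pooled[i1], pooled[rest[i2]],
                              pooled[rest[-i2]])))
    }
  } else stop("oracle handles 2 or 3 groups")
  mean(hs >= h_obs - 1e-9)
}

# Retry count by direct scan of a scripted depth series: one retry per
# completed crossing from above depth_on down past depth_off.
oracle_retries <- function(depths, depth_on = 5, depth_off = 0) {
  armed <- FALSE
  retries <- 0L
  for (d in depths) {
    if (!armed && d > depth_on) armed <- TRUE
    else if (armed && d < depth_off) {
      armed <- FALSE
      retries <- retries + 1L
    }
  }
  retries
}

# Standard two-marker color specs matching make_frame() defaults.
default_marker_specs <- function(tol = 60) {
  list(color_spec(c(220, 40, 40), tol, "proximal"),
       color_spec(c(40, 40, 220), tol, "distal"))
}

# A pair of annotated synthetic radiographs plus identity calibrations.
default_scene <- function() {
  rads <- list(AP = make_radiograph("AP"),
               CTL = make_radiograph("CTL", entry = c(60, 60),
                                     head_center = c(230, 160)))
  list(rads = rads,
       cals = list(AP = identity_affine(), CTL = identity_affine()))
}

random_affine <- function() {
  repeat {
    m <- rbind(c(runif(1, 0.5, 2), runif(1, -0.5, 0.5), runif(1, -50, 50)),
               c(runif(1, -0.5, 0.5), runif(1, 0.5, 2), runif(1, -50, 50)))
    if (abs(det(m[, 1:2])) > 0.1) return(affine2d(m))
  }
}
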