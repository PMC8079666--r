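# shared fixtures built in code

seg3_params <- function() segment_mean_params(3)

# small schedule containing TE = 15 ms as its third echo
short_schedule <- function() te_schedule(5, 5, 3)

# noisy ROI curves at given complex-noise SD (curve level)
noisy_curves <- function(params, schedule = default_schedule(), sd = 0) {
  s <- synthesize_three_pool(params, schedule)$values
  if (sd > 0)
    s <- s + complex(real = rnorm(length(s), 0, sd),
                     imaginary = rnorm(length(s), 0, sd))
  roi_curves(schedule, Mod(s) / Mod(s)[1], fdm_from_complex(s, schedule))
}

# independent exhaustive-coupling oracle for the discrete Frechet distance:
# enumerates every monotone coupling by depth-first search (feasible for
# sequences of <= ~6 points) and minimises the maximum pairwise distance
frechet_bruteforce <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  n <- nrow(p); m <- nrow(q)
  d <- function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == n && j == m) return(here)
    nxt <- Inf
    if (i < n) nxt <- min(nxt, rec(i + 1, j))
    if (j < m) nxt <- min(nxt, rec(i, j + 1))
    if (i < n && j < m) nxt <- min(nxt, rec(i + 1, j + 1))
    max(here, nxt)
  }
  rec(1, 1)
}

# random polygonal curve for property tests
random_curve <- function(n) cbind(runif(n, 0, 4), runif(n, -2, 2))
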