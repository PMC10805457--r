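#' Generate data under the global null
#'
#' Draws an n x q matrix with i.i.d. Normal(0, sigma^2) entries: the matrix
#' normal model with zero mean, under which the null hypothesis of equal
#' cluster means holds for *any* pair of estimated clusters.
#'
#' @param n,q Dimensions.
#' @param sigma Noise standard deviation.
#' @param seed Optional integer seed (local to this call).
#' @return An n x q numeric matrix.
#' @export
gen_global_null <- function(n, q, sigma = 1, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  matrix(rnorm(n * q, sd = sigma), n, q)
}

#' Generate data with three equidistant true clusters
#'
#' Three equal-sized groups whose mean vectors are pairwise at Euclidean
#' distance `delta`: the outer groups sit at `-delta/2` and `delta/2` on the
#' first coordinate, and the middle group at `sqrt(3) * delta / 2` on the
#' last coordinate (the magnitude forced by equidistance). Noise is
#' i.i.d. Normal(0, sigma^2).
#'
#' @param n Total sample size, divisible by 3.
#' @param q Number of features, at least 2.
#' @param delta Separation between population means (`delta = 0` recovers
#'   the global null).
#' @param sigma Noise standard deviation.
#' @param seed Optional integer seed (local to this call).
#' @return A list with `x` (n x q matrix), `truth` (integer labels 1..3 in
#'   blocks of n/3), and `means` (3 x q matrix of population means).
#' @export
gen_three_cluster <- function(n, q, delta, sigma = 1, seed = NULL) {
  if (n %% 3 != 0) stop("`n` must be divisible by 3", call. = FALSE)
  if (q < 2) stop("`q` must be at least 2", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  means <- matrix(0, 3, q)
  means[1, 1] <- -delta / 2
  means[2, q] <- sqrt(3) * delta / 2
  means[3, 1] <- delta / 2
  truth <- rep(1:3, each = n / 3)
  x <- means[truth, , drop = FALSE] + matrix(rnorm(n * q, sd = sigma), n, q)
  list(x = x, truth = truth, means = means)
}

#' Do two estimated clusters coincide exactly with true clusters?
#'
#' Set equality, not containment: each estimated cluster must equal some
#' true cluster as a set of observation indices. This is the detection
#' event whose frequency is the detection probability and on which the
#' conditional power conditions.
#'
#' @param members1,members2 Integer vectors: observation indices of the two
#'   estimated clusters.
#' @param truth Integer vector of true cluster labels.
#' @return Logical scalar.
#' @export
is_true_pair <- function(members1, members2, truth) {
  blocks <- split(seq_along(truth), truth)
  hit <- function(m) any(vapply(blocks, function(b) setequal(m, b),
                                logical(1)))
  hit(members1) && hit(members2)
}

# One replicate of the shared simulation core: cluster, pick a random pair,
# compute the truncation region once, and price it at several reference
# scales. Returns NULL on an empty-cluster abort (caller redraws).
sim_one <- function(x, k, sigma, tol = 1e-10) {
  trace <- tryCatch(kmeans_lloyd(x, k), error = function(e) NULL)
  if (is.null(trace)) return(NULL)
  pr <- sample.int(k, 2)                      # random pair, order irrelevant
  pair <- sort(pr)
  labels <- final_labels(trace)
  if (!all(pair %in% labels)) return(NULL)
  contrast <- contrast_vector(labels, pair[1], pair[2])
  line <- perturbation_line(x, contrast)
  stat <- line$phi_obs
  region <- truncation_region(line, trace, tol = tol)
  q <- ncol(x)
  root_nu2 <- sqrt(contrast$nu_norm2)
  p_at_scale <- function(s) {
    if (!is.finite(s) || s <= 0) return(NA_real_)
    truncated_chi_survival(stat, df = q, scale = s * root_nu2,
                           region = region)
  }
  list(pair = pair, stat = stat, trace = trace,
       p_naive = naive_p(stat, df = q, scale = sigma * root_nu2),
       p_selective = p_at_scale(sigma),
       p_selective_med = p_at_scale(sigma_med_quiet(x)),
       p_selective_sample = p_at_scale(sigma_sample(x)),
       members1 = which(labels == pair[1]),
       members2 = which(labels == pair[2]))
}

sigma_med_quiet <- function(x) suppressWarnings(sigma_med(x))

#' Global-null Type I error experiment
#'
#' Simulates datasets under the global null, clusters each with k-means,
#' tests a uniformly random pair of estimated clusters, and records four
#' p-values per replicate: naive, selective with known `sigma`, and the two
#' plug-in selective variants. Under the null the selective p-values are
#' exactly uniform, so the rejection fraction at any level estimates that
#' level; the naive p-values are stochastically much smaller.
#'
#' @param reps Number of Monte Carlo replicates.
#' @param n,q Data dimensions per replicate.
#' @param k Number of clusters.
#' @param sigma Known noise standard deviation used for generation and for
#'   the known-`sigma` p-value.
#' @param alpha Nominal level for the rejection summaries.
#' @param seed Optional integer seed for the whole experiment.
#' @return An object of class `kmeans_sim_type1`: list with `results`
#'   (tibble: `rep`, `method`, `p`, `rejected`), `summary` (tibble of
#'   rejection fractions with binomial standard errors), `redraws` (number
#'   of replicates redrawn after empty-cluster aborts) and the
#'   configuration. `tidy()` returns the per-replicate tibble; `autoplot()`
#'   draws the uniform QQ plot.
#' @export
simulate_type1 <- function(reps = 500, n = 150, q = 2, k = 3, sigma = 1,
                           alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  methods <- c("naive", "selective", "selective_med", "selective_sample")
  pmat <- matrix(NA_real_, reps, 4, dimnames = list(NULL, methods))
  redraws <- 0L
  for (r in seq_len(reps)) {
    repeat {
      x <- gen_global_null(n, q, sigma)
      one <- sim_one(x, k, sigma)
      if (!is.null(one)) break
      redraws <- redraws + 1L
    }
    pmat[r, ] <- c(one$p_naive, one$p_selective, one$p_selective_med,
                   one$p_selective_sample)
  }
  pv <- as.vector(pmat)
  results <- tibble::tibble(
    rep = rep(seq_len(reps), times = 4),
    method = rep(methods, each = reps),
    p = pv,
    rejected = pv <= alpha)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$method),
    reps = dplyr::n(),
    rejection_rate = mean(.data$rejected, na.rm = TRUE),
    se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) /
                .data$reps),
    .groups = "drop")
  structure(list(results = results, summary = summary, redraws = redraws,
                 config = list(reps = reps, n = n, q = q, k = k,
                               sigma = sigma, alpha = alpha, seed = seed)),
            class = "kmeans_sim_type1")
}

#' Detection probability and conditional power experiment
#'
#' Simulates data with three equidistant true clusters over a grid of
#' separations `delta`, clusters each dataset with k-means (`k = 3`), tests
#' a random pair of estimated clusters, and records whether the tested pair
#' coincides exactly with true clusters (detection) and whether each
#' selective p-value rejects. The detection probability is the fraction of
#' replicates where the tested clusters are true clusters; the conditional
#' power is the rejection rate among those replicates (reported `NA` when
#' none detected).
#'
#' @param delta Numeric vector of mean separations.
#' @param reps Replicates per `delta`.
#' @param n,q Data dimensions (n divisible by 3).
#' @param k Number of clusters (default 3, matching the generator).
#' @param sigma Noise standard deviation.
#' @param alpha Nominal level.
#' @param seed Optional integer seed.
#' @return An object of class `kmeans_sim_power`: `results` (tibble per
#'   replicate and method) and `summary` (tibble per `delta` and method
#'   with `detection_prob` and `conditional_power`).
#' @export
simulate_power <- function(delta = c(4, 6, 8, 10), reps = 2000, n = 150,
                           q = 10, k = 3, sigma = 0.25, alpha = 0.05,
                           seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  methods <- c("selective", "selective_med", "selective_sample")
  rows <- vector("list", length(delta))
  redraws <- 0L
  for (di in seq_along(delta)) {
    d <- delta[di]
    pmat <- matrix(NA_real_, reps, 3, dimnames = list(NULL, methods))
    det <- logical(reps)
    for (r in seq_len(reps)) {
      repeat {
        g <- gen_three_cluster(n, q, d, sigma)
        one <- sim_one(g$x, k, sigma)
        if (!is.null(one)) break
        redraws <- redraws + 1L
      }
      det[r] <- is_true_pair(one$members1, one$members2, g$truth)
      pmat[r, ] <- c(one$p_selective, one$p_selective_med,
                     one$p_selective_sample)
    }
    pv <- as.vector(pmat)
    rows[[di]] <- tibble::tibble(
      delta = d,
      rep = rep(seq_len(reps), times = 3),
      method = rep(methods, each = reps),
      p = pv,
      rejected = pv <= alpha,
      detected = rep(det, times = 3))
  }
  results <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$delta, .data$method),
    reps = dplyr::n(),
    detection_prob = mean(.data$detected),
    conditional_power = if (any(.data$detected))
      mean(.data$rejected[.data$detected], na.rm = TRUE) else NA_real_,
    .groups = "drop")
  structure(list(results = results, summary = summary, redraws = redraws,
                 config = list(delta = delta, reps = reps, n = n, q = q,
                               k = k, sigma = sigma, alpha = alpha,
                               seed = seed)),
            class = "kmeans_sim_power")
}

#' @export
print.kmeans_sim_type1 <- function(x, ...) {
  cat(sprintf(
    "<kmeans_sim_type1> %d replicates, n = %d, q = %d, k = %d, alpha = %g\n",
    x$config$reps, x$config$n, x$config$q, x$config$k, x$config$alpha))
  print(x$summary)
  invisible(x)
}

#' @export
print.kmeans_sim_power <- function(x, ...) {
  cat(sprintf(
    "<kmeans_sim_power> %d replicates per delta, n = %d, q = %d, sigma = %g\n",
    x$config$reps, x$config$n, x$config$q, x$config$sigma))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @method tidy kmeans_sim_type1
#' @export
tidy.kmeans_sim_type1 <- function(x, ...) x$results

#' @method tidy kmeans_sim_power
#' @export
tidy.kmeans_sim_power <- function(x, ...) x$results

#' @method glance kmeans_sim_type1
#' @export
glance.kmeans_sim_type1 <- function(x, ...) {
  wide <- stats::setNames(x$summary$rejection_rate,
                          paste0("reject_", x$summary$method))
  dplyr::bind_cols(tibble::as_tibble(as.list(wide)),
                   tibble::as_tibble(x$config[c("reps", "n", "q", "k",
                                                "sigma", "alpha")]))
}

#' @method glance kmeans_sim_power
#' @export
glance.kmeans_sim_power <- function(x, ...) {
  tibble::tibble(n_delta = length(x$config$delta),
                 reps = x$config$reps, n = x$config$n, q = x$config$q,
                 sigma = x$config$sigma, alpha = x$config$alpha,
                 redraws = x$redraws)
}
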