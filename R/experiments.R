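#' Wilson score interval for a binomial proportion
#'
#' 95% (by default) Wilson score interval, well-behaved for proportions
#' near 0 and 1 where most rescue-probability estimates live. Delegates to
#' [stats::prop.test()] without continuity correction.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  # the chi-squared small-count warning concerns the test statistic, not
  # the score interval used here
  ci <- suppressWarnings(stats::prop.test(k, n, conf.level = conf,
                                          correct = FALSE)$conf.int)
  as.numeric(ci)
}

# documented seed-spawning scheme: replicate i of a batch started at
# `master_seed` uses set.seed((master_seed + i - 1) mod (2^31 - 1))
replicate_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + i - 1) %% 2147483647)
}

# deterministic short id of a parameter set (polynomial rolling hash of its
# flat serialized form)
params_id <- function(p) {
  s <- paste(vapply(params_to_list(p), function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Monte Carlo estimate of the rescue probability
#'
#' Runs `n_replicates` independent simulations (per-replicate seeds derived
#' from `master_seed` by replicate index) and returns the fraction that
#' resulted in rescue with a 95% Wilson confidence interval. Runs that are
#' undecided at `t_max` are counted as non-rescues and reported.
#'
#' @param p a [rescue_params()] object.
#' @param n_replicates number of replicate simulations (>= 1).
#' @param master_seed integer master seed.
#' @return one-row data frame with columns `params_id`, `model_variant`,
#'   `n_replicates`, `n_rescued`, `n_undecided`, `p_hat`, `ci_low`,
#'   `ci_high`, `seed`.
#' @examples
#' p <- rescue_params("cooperation", N_c = 50, mu = 1e-3)
#' estimate_rescue_probability(p, n_replicates = 20, master_seed = 1)
#' @export
estimate_rescue_probability <- function(p, n_replicates = 1000,
                                        master_seed = 1) {
  validate_params(p)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  n_rescued <- 0L; n_undecided <- 0L
  for (i in seq_len(n_replicates)) {
    out <- run_simulation(p, seed = replicate_seed(master_seed, i),
                          record_stride = 0L)
    if (out$verdict == "rescued") n_rescued <- n_rescued + 1L
    if (out$verdict == "undecided_at_t_max") n_undecided <- n_undecided + 1L
  }
  ci <- wilson_ci(n_rescued, n_replicates)
  data.frame(params_id = params_id(p), model_variant = p$model_variant,
             n_replicates = n_replicates, n_rescued = n_rescued,
             n_undecided = n_undecided, p_hat = n_rescued / n_replicates,
             ci_low = ci[1], ci_high = ci[2], seed = master_seed,
             stringsAsFactors = FALSE)
}

#' Rescue-probability sweep over a parameter grid
#'
#' One [estimate_rescue_probability()] row per grid point. Each grid row
#' gets its own master seed (`master_seed + (row - 1) * n_replicates`) so
#' replicate streams never overlap across rows, and rows are independent of
#' evaluation order.
#'
#' @param grid data frame whose columns name parameters to override in
#'   `base_params` (one row per grid point).
#' @param base_params a [rescue_params()] object giving the fixed values.
#' @param n_replicates replicates per grid point.
#' @param master_seed integer master seed.
#' @param rows optional subset of grid row indices to evaluate (used for
#'   checkpoint resumption); seeds depend only on the row index.
#' @return data frame of class `sweep_result`: the grid columns, a
#'   `grid_row` index, and the estimate columns.
#' @export
rescue_sweep <- function(grid, base_params, n_replicates = 1000,
                         master_seed = 1, rows = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  if (is.null(rows)) rows <- seq_len(nrow(grid))
  out <- lapply(rows, function(i) {
    p <- tryCatch(
      do.call(update_params,
              c(list(base_params), as.list(grid[i, , drop = FALSE]))),
      error = function(e) stop("invalid grid point ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    row_seed <- master_seed + (i - 1) * n_replicates
    cbind(grid_row = i, grid[i, , drop = FALSE],
          estimate_rescue_probability(p, n_replicates, row_seed),
          row.names = NULL)
  })
  res <- do.call(rbind, out)
  class(res) <- c("sweep_result", class(res))
  attr(res, "master_seed") <- master_seed
  res
}

.family_order <- c("baseline", "cooperation", "mutualism_no_competition",
                   "mutualism", "cheater")

#' Compare rescue probabilities across the model families
#'
#' Evaluates every model variant on each point of a shared grid, plus the
#' derived quantity `cooperation_squared` (the rescue probability of two
#' independent cooperating populations, against which mutualism without
#' competition is compared). Confidence bounds for the squared estimate are
#' the squared Wilson bounds.
#'
#' @inheritParams rescue_sweep
#' @return long data frame: `grid_row`, the grid columns, `family`, and the
#'   estimate columns.
#' @export
compare_model_families <- function(grid, base_params, n_replicates = 500,
                                   master_seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    fam_rows <- list()
    for (k in seq_along(.family_order)) {
      fam <- .family_order[k]
      p <- do.call(update_params,
                   c(list(base_params), as.list(grid[i, , drop = FALSE]),
                     list(model_variant = fam)))
      seed_ik <- master_seed + ((i - 1) * length(.family_order) + (k - 1)) *
        n_replicates
      est <- estimate_rescue_probability(p, n_replicates, seed_ik)
      est$family <- fam
      fam_rows[[fam]] <- est
    }
    co <- fam_rows[["cooperation"]]
    sq <- co
    sq$family <- "cooperation_squared"
    sq$p_hat <- co$p_hat^2
    sq$ci_low <- co$ci_low^2
    sq$ci_high <- co$ci_high^2
    sq$n_rescued <- NA_integer_
    fam_rows[["cooperation_squared"]] <- sq
    block <- do.call(rbind, fam_rows)
    out[[i]] <- cbind(grid_row = i, grid[i, , drop = FALSE], block,
                      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Growth-rate multiplier equalizing rescue probabilities of two families
#'
#' Finds the factor `c` by which both growth rates (`r_A`, `r_M`) of the
#' handicapped family must be multiplied for its rescue probability to
#' match the reference family's, by monotone bisection on
#' `c` in `bracket` (rescue probability is monotone in the growth
#' multiplier). Stopping is confidence-aware: bisection ends when the two
#' estimates differ by at most `tol` or the bracket is narrower than 0.01.
#'
#' @param base_params a [rescue_params()] object; growth rates of the
#'   handicapped family are `c * r_A`, `c * r_M`.
#' @param family_pair character vector
#'   `c(handicapped_variant, reference_variant)`, e.g.
#'   `c("cooperation", "baseline")`.
#' @param n_replicates replicates per probability evaluation.
#' @param tol probability tolerance declaring the two estimates equal;
#'   default `1.96 * sqrt(2 * 0.25 / n_replicates) + 0.01` (a conservative
#'   binomial standard-error band).
#' @param master_seed integer master seed.
#' @param bracket search interval for the multiplier.
#' @return the multiplier, with attributes `p_ref` and `p_matched`; `NA`
#'   (with attribute `reason`) when no matching ratio exists in the
#'   bracket, which happens in particular when the reference probability is
#'   zero.
#' @export
matched_growth_ratio <- function(base_params,
                                 family_pair = c("cooperation", "baseline"),
                                 n_replicates = 200, tol = NULL,
                                 master_seed = 1, bracket = c(1, 4)) {
  stopifnot(length(family_pair) == 2,
            all(family_pair %in% .variant_levels))
  if (is.null(tol)) tol <- 1.96 * sqrt(2 * 0.25 / n_replicates) + 0.01

  p_ref_params <- update_params(base_params,
                                model_variant = family_pair[2])
  ref <- estimate_rescue_probability(p_ref_params, n_replicates,
                                     master_seed)
  if (ref$n_rescued == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "reference rescue probability is zero"
    attr(out, "p_ref") <- ref$p_hat
    return(out)
  }

  eval_c <- local({
    counter <- 0
    function(cc) {
      counter <<- counter + 1
      ph <- update_params(base_params, model_variant = family_pair[1],
                          r_A = cc * base_params$r_A,
                          r_M = cc * base_params$r_M)
      estimate_rescue_probability(
        ph, n_replicates,
        master_seed + counter * (n_replicates + 1))$p_hat
    }
  })

  lo <- bracket[1]; hi <- bracket[2]
  p_lo <- eval_c(lo)
  if (p_lo >= ref$p_hat - tol) {
    out <- lo
    attr(out, "p_ref") <- ref$p_hat; attr(out, "p_matched") <- p_lo
    return(out)
  }
  p_hi <- eval_c(hi)
  if (p_hi < ref$p_hat - tol) {
    out <- NA_real_
    attr(out, "reason") <- "no matching ratio in the search bracket"
    attr(out, "p_ref") <- ref$p_hat
    return(out)
  }
  p_mid <- NA_real_
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    p_mid <- eval_c(mid)
    if (abs(p_mid - ref$p_hat) <= tol) { lo <- mid; hi <- mid; break }
    if (p_mid < ref$p_hat) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "p_ref") <- ref$p_hat
  attr(out, "p_matched") <- p_mid
  out
}
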