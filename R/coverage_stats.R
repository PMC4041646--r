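## Cramer-von Mises two-sample statistic on pooled ECDFs:
## T = n*m/(n+m)^2 * sum_i (F_x(z_i) - F_y(z_i))^2 over all pooled points.
## `ord` and tie bookkeeping are precomputed once so permutations only pay
## a cumsum; `is_x_sorted` marks which pooled (sorted) entries belong to x.
cvm_stat_sorted <- function(is_x_sorted, n, m, tie_last) {
  Fx <- cumsum(is_x_sorted)[tie_last] / n
  Fy <- cumsum(!is_x_sorted)[tie_last] / m
  n * m / (n + m)^2 * sum((Fx - Fy)^2)
}

#' Two-sample Cramer-von Mises test with permutation p-value
#'
#' The statistic is `T = nm/(n+m)^2 * sum_i (F_x(z_i) - F_y(z_i))^2`,
#' summed over all pooled observations `z_i` with `F_x`, `F_y` the two
#' empirical CDFs (ties handled by evaluating both CDFs at each pooled
#' point, with multiplicity). The p-value is obtained by randomly
#' relabelling the pooled sample: `p = (1 + #{T_perm >= T_obs}) /
#' (1 + n_perm)`. With `exact = TRUE` (feasible only for small samples)
#' all distinct relabellings are enumerated and
#' `p = #{T >= T_obs} / n_combinations`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param n_perm Number of random permutations.
#' @param seed Integer seed for the permutations.
#' @param exact Enumerate all `choose(n+m, n)` relabellings instead of
#'   sampling (requires `choose(n+m, n) <= 1e5`).
#' @return One-row tibble of class `cvm_result`: `statistic`, `p_value`,
#'   `n_perm`, `n_x`, `n_y`, `exact`.
#' @export
#' @examples
#' cvm_two_sample(c(1, 2), c(3, 4), exact = TRUE)
cvm_two_sample <- function(x, y, n_perm = 9999, seed = 1L, exact = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(statistic = 0, p_value = 1,
                          n_perm = if (exact) choose(n + m, n) else n_perm,
                          n_x = n, n_y = m, exact = exact))
  }
  ord <- order(pooled)
  sorted <- pooled[ord]
  ## last index of each tie group, mapped back to every member
  ends <- which(c(sorted[-1] != sorted[-(n + m)], TRUE))
  last_of_group <- rep.int(ends, diff(c(0L, ends)))
  is_x <- ord <= n
  t_obs <- cvm_stat_sorted(is_x, n, m, last_of_group)

  stat_for <- function(x_idx) {
    lab <- logical(n + m)
    lab[x_idx] <- TRUE
    cvm_stat_sorted(lab, n, m, last_of_group)
  }

  if (exact) {
    if (choose(n + m, n) > 1e5) {
      stop("exact enumeration limited to choose(n+m, n) <= 1e5",
           call. = FALSE)
    }
    combos <- utils::combn(n + m, n)
    stats <- apply(combos, 2L, stat_for)
    p <- mean(stats >= t_obs - 1e-12)
    n_eff <- ncol(combos)
  } else {
    stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        stat_for(sample.int(n + m, n))
      }, 0)
    })
    p <- (1 + sum(stats >= t_obs - 1e-12)) / (1 + n_perm)
    n_eff <- n_perm
  }
  tibble::tibble(statistic = t_obs, p_value = p, n_perm = n_eff,
                 n_x = n, n_y = m, exact = exact)
}

#' Goodness-of-fit comparison against a reference sample
#'
#' Semantic alias of [cvm_two_sample()] for comparing an observed sample
#' (e.g. a k-mer relative-abundance distribution) against a reference
#' sample such as the artificial null genome's distribution; the reference
#' is treated as the second sample.
#'
#' @param sample,reference_sample Numeric samples.
#' @inheritParams cvm_two_sample
#' @return As [cvm_two_sample()].
#' @export
cvm_gof <- function(sample, reference_sample, n_perm = 9999, seed = 1L,
                    exact = FALSE) {
  cvm_two_sample(sample, reference_sample, n_perm = n_perm, seed = seed,
                 exact = exact)
}

#' Kruskal-Wallis rank-sum test over groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on
#' `groups - 1` degrees of freedom (computed by [stats::kruskal.test()]).
#'
#' @param groups List of numeric samples (>= 2 groups, each nonempty).
#' @return One-row tibble: `H`, `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    return(tibble::tibble(H = 0, df = length(groups) - 1L, p_value = 1))
  }
  g <- factor(rep.int(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value)
}

#' Compare two coverage tracks by repeated subsampling
#'
#' For each of `n_rep` replicates, `sample_size` positions are drawn
#' uniformly without replacement from each track's per-base depth vector
#' and the two depth samples are compared with [cvm_two_sample()].
#' Identical underlying distributions give p-values centred on uniform;
#' amplification-biased coverage against uniform coverage drives the
#' median p-value to the test's floor.
#'
#' @param track_a,track_b [coverage_track()] objects over the same
#'   reference.
#' @param n_rep Number of subsampling replicates.
#' @param sample_size Positions drawn per track per replicate (at most the
#'   reference length).
#' @param seed Integer seed.
#' @param n_perm Permutations per replicate test.
#' @param pooled Also run one test on the full depth vectors (reported in
#'   `glance`-style attributes).
#' @return Tibble of class `subsample_comparison` with one row per
#'   replicate (`rep`, `statistic`, `p_value`) and attributes
#'   `median_p`, `pooled_statistic`, `pooled_p`.
#' @export
subsample_compare <- function(track_a, track_b, n_rep = 100,
                              sample_size = 1000, seed = 1L, n_perm = 499,
                              pooled = FALSE) {
  stopifnot(inherits(track_a, "coverage_track"),
            inherits(track_b, "coverage_track"))
  la <- length(track_a$depth)
  lb <- length(track_b$depth)
  if (sample_size > la || sample_size > lb) {
    stop("sample_size exceeds reference length", call. = FALSE)
  }
  res <- withr::with_seed(seed, {
    purrr::map(seq_len(n_rep), function(r) {
      xa <- track_a$depth[sample.int(la, sample_size)]
      xb <- track_b$depth[sample.int(lb, sample_size)]
      cvm_two_sample(xa, xb, n_perm = n_perm,
                     seed = sample.int(.Machine$integer.max, 1))
    })
  })
  out <- tibble::tibble(
    rep = seq_len(n_rep),
    statistic = purrr::map_dbl(res, "statistic"),
    p_value = purrr::map_dbl(res, "p_value"))
  attr(out, "median_p") <- stats::median(out$p_value)
  if (pooled) {
    pt <- cvm_two_sample(track_a$depth, track_b$depth, n_perm = n_perm,
                         seed = seed)
    attr(out, "pooled_statistic") <- pt$statistic
    attr(out, "pooled_p") <- pt$p_value
  }
  class(out) <- c("subsample_comparison", class(out))
  out
}

#' Summarise a subsample comparison
#'
#' @param x A [subsample_compare()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_rep`, `median_p`, `median_statistic`, and
#'   pooled results when present.
#' @export
glance.subsample_comparison <- function(x, ...) {
  tibble::tibble(
    n_rep = nrow(x),
    median_p = attr(x, "median_p"),
    median_statistic = stats::median(x$statistic),
    pooled_statistic = attr(x, "pooled_statistic") %||% NA_real_,
    pooled_p = attr(x, "pooled_p") %||% NA_real_)
}

#' Write per-replicate comparison statistics as TSV
#'
#' @param x A [subsample_compare()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
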