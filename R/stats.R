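#' Resampling configuration
#'
#' @param n_boot Bootstrap replicates (default 5000).
#' @param n_perm Permutation replicates (default 5000); exhaustive
#'   enumeration automatically replaces Monte-Carlo when the permutation
#'   space is not larger than `n_perm`.
#' @param subsample_to If set, each permutation first randomly subsamples
#'   groups larger than this to this many trials (used to equalize sample
#'   sizes for Brain-condition comparisons, 80 trials in the original
#'   protocol).
#' @param seed Integer seed recorded in all outputs; identical seeds give
#'   identical results.
#' @return An `al_stats_config` object.
#' @export
stats_config <- function(n_boot = 5000, n_perm = 5000, subsample_to = NULL,
                         seed = 1L) {
  stopifnot(n_boot >= 1, n_perm >= 1)
  structure(list(n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 subsample_to = subsample_to, seed = as.integer(seed)),
            class = "al_stats_config")
}

new_stat <- function(scheme, observed, dist, p, p_above = NA_real_,
                     p_below = NA_real_, ci = c(NA_real_, NA_real_),
                     n = NA_integer_, n_draws = NA_integer_, seed = NA_integer_,
                     exhaustive = FALSE, comparison = NA_character_) {
  structure(list(scheme = scheme, observed = observed, dist = dist,
                 p = p, p_above = p_above, p_below = p_below,
                 ci = ci, n = n, n_draws = n_draws, seed = seed,
                 exhaustive = exhaustive, comparison = comparison),
            class = "al_stat")
}

#' @export
print.al_stat <- function(x, ...) {
  cat(sprintf("<%s> observed = %.4g dB, p = %.4g (n = %s, draws = %d%s)\n",
              x$scheme, x$observed, x$p, paste(x$n, collapse = "+"),
              x$n_draws, if (x$exhaustive) ", exhaustive" else ""))
  if (all(is.finite(x$ci))) {
    cat(sprintf("  95%% CI [%.4g, %.4g]; mass above 0 = %.4g, below = %.4g\n",
                x$ci[1], x$ci[2], x$p_above, x$p_below))
  }
  invisible(x)
}

# resolve scalar-vector vs band-tensor input into (statistic closure, n)
stat_input <- function(x) {
  if (inherits(x, "al_band_tensor")) {
    list(fun = function(idx) tensor_summary(x, idx), n = x$n_trials)
  } else {
    x <- as.numeric(x)
    list(fun = function(idx) {
      rowMeans(matrix(x[t(idx)], nrow = nrow(idx), byrow = TRUE))
    }, n = length(x))
  }
}

#' Bootstrap test of a mean effect against zero
#'
#' Resamples trials with replacement and recomputes the summary per draw
#' (for band tensors the across-epoch median, baseline median and dB
#' conversion are recomputed within every draw), yielding a confidence
#' distribution for the mean effect. Both one-sided fractional masses of the
#' distribution above and below zero are reported; the headline p-value is
#' `2 * min(mass_above, mass_below)` capped at 1.
#'
#' @param x Per-trial effect values (numeric) or an `al_band_tensor`.
#' @param cfg An `al_stats_config`.
#' @return An `al_stat` with scheme `"bootstrap_vs_zero"`.
#' @export
bootstrap_vs_zero <- function(x, cfg = stats_config()) {
  inp <- stat_input(x)
  if (inp$n < 2) stop("bootstrap_vs_zero: need >= 2 trials")
  observed <- inp$fun(matrix(seq_len(inp$n), nrow = 1))
  boot <- withr::with_seed(cfg$seed, {
    idx <- matrix(sample.int(inp$n, inp$n * cfg$n_boot, replace = TRUE),
                  nrow = cfg$n_boot)
    inp$fun(idx)
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  if (diff(ci) == 0) {
    warning("bootstrap_vs_zero: degenerate (all-equal) bootstrap distribution")
  }
  above <- mean(boot > 0); below <- mean(boot < 0)
  new_stat("bootstrap_vs_zero", observed, boot,
           p = min(1, 2 * min(above, below)),
           p_above = above, p_below = below, ci = ci,
           n = inp$n, n_draws = cfg$n_boot, seed = cfg$seed)
}

#' Permutation test for a difference between two conditions
#'
#' Permutes condition labels over the pooled trials and recomputes the
#' difference in summaries per draw. The p-value is the fraction of null
#' values whose absolute value is at least the absolute observed difference
#' (no small-sample `+1` correction — the fraction is taken literally).
#' When `cfg$subsample_to` is set, each permutation first subsamples larger
#' groups to that size; the observed difference uses the full groups. When
#' the number of distinct label assignments does not exceed `cfg$n_perm`
#' (and no subsampling is requested), all assignments are enumerated.
#'
#' @param a,b Per-trial values (numeric) or `al_band_tensor`s with identical
#'   column structure (same band, baseline, window).
#' @param cfg An `al_stats_config`.
#' @return An `al_stat` with scheme `"perm_condition"`.
#' @export
perm_condition <- function(a, b, cfg = stats_config()) {
  pooled <- pool_two(a, b)
  na <- pooled$na; nb <- pooled$nb; n <- na + nb
  if (na < 2 || nb < 2) stop("perm_condition: both groups need >= 2 trials")
  fun <- pooled$fun
  observed <- fun(matrix(seq_len(na), nrow = 1)) -
    fun(matrix(na + seq_len(nb), nrow = 1))
  sub <- cfg$subsample_to
  exhaustive <- is.null(sub) && choose(n, na) <= cfg$n_perm
  null_dist <- withr::with_seed(cfg$seed, {
    if (exhaustive) {
      combs <- utils::combn(n, na)
      apply(combs, 2, function(ia) {
        fun(matrix(ia, nrow = 1)) - fun(matrix(setdiff(seq_len(n), ia), nrow = 1))
      })
    } else {
      vapply(seq_len(cfg$n_perm), function(i) {
        perm <- sample.int(n)
        ia <- perm[seq_len(na)]; ib <- perm[na + seq_len(nb)]
        if (!is.null(sub)) {
          if (length(ia) > sub) ia <- sample(ia, sub)
          if (length(ib) > sub) ib <- sample(ib, sub)
        }
        fun(matrix(ia, nrow = 1)) - fun(matrix(ib, nrow = 1))
      }, numeric(1))
    }
  })
  p <- mean(abs(null_dist) >= abs(observed))
  new_stat("perm_condition", observed, null_dist, p = p,
           n = c(na, nb), n_draws = length(null_dist), seed = cfg$seed,
           exhaustive = exhaustive)
}

# pool two inputs (both numeric or both tensors) into one statistic closure
pool_two <- function(a, b) {
  if (inherits(a, "al_band_tensor") && inherits(b, "al_band_tensor")) {
    if (!identical(a$colfreq, b$colfreq) || !identical(a$coltype, b$coltype)) {
      stop("perm_condition: tensors have different column structure")
    }
    merged <- a
    merged$X <- rbind(a$X, b$X)
    merged$n_trials <- a$n_trials + b$n_trials
    list(fun = function(idx) tensor_summary(merged, idx),
         na = a$n_trials, nb = b$n_trials)
  } else {
    x <- c(as.numeric(a), as.numeric(b))
    list(fun = function(idx) {
      rowMeans(matrix(x[t(idx)], nrow = nrow(idx), byrow = TRUE))
    }, na = length(a), nb = length(b))
  }
}

#' Permutation test for a difference between two arrays
#'
#' The unit of exchange is the electrode: array-membership labels are
#' shuffled across electrodes and the difference of array means of the
#' per-electrode post-stimulation band power recomputed per draw. Two-sided
#' p-value as in [perm_condition()]; exhaustive when feasible.
#'
#' @param values Per-electrode summary values (dB).
#' @param arrays Array label per electrode (exactly two distinct labels).
#' @param cfg An `al_stats_config`.
#' @return An `al_stat` with scheme `"perm_array"`.
#' @export
perm_array <- function(values, arrays, cfg = stats_config()) {
  arrays <- as.factor(arrays)
  if (nlevels(arrays) != 2) stop("perm_array: need exactly two arrays")
  ga <- values[arrays == levels(arrays)[1]]
  gb <- values[arrays == levels(arrays)[2]]
  if (length(ga) < 2 || length(gb) < 2) {
    stop("perm_array: need >= 2 electrodes per array")
  }
  res <- perm_condition(ga, gb, cfg)
  res$scheme <- "perm_array"
  res
}

#' Benjamini-Hochberg FDR correction within declared families
#'
#' Step-up adjusted p-values computed independently within each family (the
#' original analysis corrected across the 3 pairwise condition comparisons
#' within each frequency band).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param family Optional vector of family labels, same length as `p`;
#'   `NULL` treats all p-values as one family.
#' @return Adjusted p-values, same order as `p`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
fdr_bh <- function(p, family = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  out <- p
  for (f in unique(family)) {
    sel <- family == f
    out[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a resampling result
#'
#' One row per result: observed effect, confidence bounds, p-values, draw
#' counts and seed.
#'
#' @param x An `al_stat`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy al_stat
#' @export
tidy.al_stat <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    estimate = x$observed,
    conf.low = x$ci[1], conf.high = x$ci[2],
    p.value = x$p, p.above = x$p_above, p.below = x$p_below,
    n = paste(x$n, collapse = "+"),
    n.draws = x$n_draws, exhaustive = x$exhaustive, seed = x$seed
  )
}

#' @rdname tidy.al_stat
#' @method glance al_stat
#' @export
glance.al_stat <- function(x, ...) tidy(x, ...)
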