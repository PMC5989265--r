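#' @importFrom stats nls nls.control optim quantile coef fitted
NULL

#' Convert developmental age labels to log10 post-conception days
#'
#' Labels of the form `E<d>` (embryonic day, already post-conception),
#' `P<d>` (postnatal day, shifted by the gestation length) or `<n>mo`
#' (postnatal months) are mapped to post-conception days and log10
#' transformed, giving the time axis on which splicing switches are
#' parameterized.
#'
#' @param labels character vector of age labels.
#' @param gestation_days mouse gestation length in days (default 19.5), so
#'   P0 sits at 19.5 post-conception days.
#' @param days_per_month mean month length (default 30.44).
#' @return named numeric vector of log10 post-conception days.
#' @examples
#' toLog10Pcdays(c("E14.5", "P0", "4mo"))
#' @export
toLog10Pcdays <- function(labels, gestation_days = 19.5,
                          days_per_month = 30.44) {
    labels <- as.character(labels)
    pcd <- vapply(labels, function(lab) {
        if (grepl("^E[0-9]+(\\.[0-9]+)?$", lab))
            as.numeric(sub("^E", "", lab))
        else if (grepl("^P[0-9]+(\\.[0-9]+)?$", lab))
            gestation_days + as.numeric(sub("^P", "", lab))
        else if (grepl("^[0-9]+(\\.[0-9]+)?mo$", lab))
            gestation_days + days_per_month * as.numeric(sub("mo$", "", lab))
        else stop(sprintf("cannot parse age label '%s' (expect E<d>, P<d> or <n>mo)", lab))
    }, numeric(1))
    log10(pcd)
}

#' Sigmoidal inclusion trajectory
#'
#' `psi(t) = a + (k - a) / (1 + exp(-b (t - m)))`: `a` and `k` are the low
#' and high inclusion levels, `b` the slope (its sign carries the switch
#' direction) and `m` the time of the maximal splicing switch in log10
#' post-conception days.
#'
#' @param t time(s), log10 post-conception days.
#' @param a,k low and high inclusion levels.
#' @param b slope.
#' @param m switch midpoint.
#' @return inclusion level(s).
#' @export
sigmoidPsi <- function(t, a, k, b, m) a + (k - a) / (1 + exp(-b * (t - m)))

#' Normalized residual of a sigmoid fit
#'
#' `epsilon = sqrt( sum_i (psi_i - fitted_i)^2 / (N * (k - a)) )` with `N`
#' the number of non-missing time points. Normalizing by the switch range
#' `k - a` makes the score comparable across exons of different dynamic
#' range; a degenerate range (`k - a <= 0`) yields `Inf` so the fit can
#' never be called reliable.
#'
#' @param observed,fitted aligned trajectories (missing observed values are
#'   dropped pairwise).
#' @param range the fitted switch range `k - a`.
#' @return epsilon >= 0 (possibly `Inf`).
#' @export
normalizedResidual <- function(observed, fitted, range) {
    keep <- !is.na(observed)
    observed <- observed[keep]
    fitted <- fitted[keep]
    if (!length(observed)) return(Inf)
    if (!is.finite(range) || range <= 0) return(Inf)
    sqrt(sum((observed - fitted)^2) / (length(observed) * range))
}

#' Fit the sigmoidal switch model to one inclusion trajectory
#'
#' Nonlinear least squares (the "port" algorithm, with a bounded
#' quasi-Newton fallback) under box constraints `a, k` in \[0, 1\] and `m`
#' within the observed time range widened by 0.5 log10-days. Optimization is
#' multi-start: `m` is initialized at the time the trajectory crosses the
#' midpoint of its observed range and at the 25/50/75% quantiles of the time
#' axis, each with slopes +4 and -4; the start with the smallest residual
#' sum of squares wins. Afterward the parameterization is normalized so that
#' `a <= k` (swapping `a`/`k` and negating `b` is an exact identity of the
#' model), leaving the direction of the switch entirely in `sign(b)`.
#'
#' The fit is `reliable` when `epsilon < eps_max`, `k - a > min_range` and
#' `m > min_m` (defaults 0.15, 0.2, 0).
#'
#' @param traj inclusion levels (may contain `NA`).
#' @param times numeric time axis (log10 post-conception days) or character
#'   age labels passed through [toLog10Pcdays()].
#' @param min_points minimum non-missing points to attempt a fit (default 5).
#' @param eps_max,min_range,min_m reliability thresholds.
#' @return one-row data.frame: `a`, `k`, `b`, `m`, `epsilon`, `n_points`,
#'   `converged`, `reliable`.
#' @examples
#' tt <- toLog10Pcdays(c("E14.5", "E16.5", "P0", "P4", "P7",
#'                       "P15", "P30", "4mo", "21mo"))
#' y <- sigmoidPsi(tt, 0.1, 0.9, 8, 1.3)
#' fitSigmoid(y, tt)
#' @export
fitSigmoid <- function(traj, times, min_points = 5,
                       eps_max = 0.15, min_range = 0.2, min_m = 0) {
    if (is.character(times)) times <- toLog10Pcdays(times)
    stopifnot(length(traj) == length(times))
    keep <- !is.na(traj)
    empty <- data.frame(a = NA_real_, k = NA_real_, b = NA_real_,
                        m = NA_real_, epsilon = Inf,
                        n_points = sum(keep), converged = FALSE,
                        reliable = FALSE)
    if (sum(keep) < min_points) return(empty)
    y <- as.numeric(traj[keep])
    t <- as.numeric(times[keep])
    mlo <- min(t) - 0.5
    mhi <- max(t) + 0.5
    ylo <- min(y); yhi <- max(y)
    # m start: first crossing of the observed half-range
    half <- (ylo + yhi) / 2
    cross <- which(diff(sign(y - half)) != 0)
    m0 <- if (length(cross)) mean(t[cross[1L] + 0:1]) else mean(t)
    starts <- expand.grid(m = unique(c(m0, quantile(t, c(0.25, 0.5, 0.75),
                                                    names = FALSE))),
                          b = c(4, -4))
    best <- NULL
    bestSse <- Inf
    for (s in seq_len(nrow(starts))) {
        init <- c(a = ylo, k = yhi, b = starts$b[s], m = starts$m[s])
        fit <- .sigmoidLsq(y, t, init, mlo, mhi)
        if (!is.null(fit) && fit$sse < bestSse - 1e-12) {
            best <- fit
            bestSse <- fit$sse
        }
    }
    if (is.null(best)) return(empty)
    pars <- best$par
    if (pars["a"] > pars["k"]) {  # normalize: a = low, k = high, flip slope
        pars[c("a", "k")] <- pars[c("k", "a")]
        pars["b"] <- -pars["b"]
    }
    fit_vals <- sigmoidPsi(t, pars["a"], pars["k"], pars["b"], pars["m"])
    eps <- normalizedResidual(y, fit_vals, pars["k"] - pars["a"])
    data.frame(a = unname(pars["a"]), k = unname(pars["k"]),
               b = unname(pars["b"]), m = unname(pars["m"]),
               epsilon = eps, n_points = length(y), converged = TRUE,
               reliable = is.finite(eps) & eps < eps_max &
                   (pars["k"] - pars["a"]) > min_range & pars["m"] > min_m)
}

.sigmoidLsq <- function(y, t, init, mlo, mhi) {
    lower <- c(a = 0, k = 0, b = -200, m = mlo)
    upper <- c(a = 1, k = 1, b = 200, m = mhi)
    init <- pmin(pmax(init, lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
        suppressWarnings(
            nls(y ~ a + (k - a) / (1 + exp(-b * (t - m))),
                start = as.list(init), algorithm = "port",
                lower = lower, upper = upper,
                control = nls.control(maxiter = 200, warnOnly = TRUE))),
        error = function(e) NULL)
    if (!is.null(fit)) {
        par <- coef(fit)
        return(list(par = par, sse = sum((y - fitted(fit))^2)))
    }
    sse_fun <- function(p) {
        r <- y - sigmoidPsi(t, p[1], p[2], p[3], p[4])
        sum(r * r)
    }
    o <- tryCatch(optim(init, sse_fun, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (is.null(o)) return(NULL)
    list(par = setNames(o$par, names(init)), sse = o$value)
}

#' Fit the sigmoid model to every exon of a PSI matrix
#'
#' @param psi a [PsiExperiment-class] or psi matrix (exons x time points).
#' @param times time axis: numeric log10 post-conception days or age labels;
#'   defaults to parsing the column names.
#' @param ... passed to [fitSigmoid()].
#' @return data.frame with one row per exon (`exon_id` first column).
#' @export
fitSigmoidMatrix <- function(psi, times = NULL, ...) {
    m <- if (is(psi, "PsiExperiment")) psiValues(psi) else as.matrix(psi)
    if (is.null(times)) times <- colnames(m)
    if (is.character(times)) times <- toLog10Pcdays(times)
    rows <- lapply(seq_len(nrow(m)), function(i)
        fitSigmoid(m[i, ], times, ...))
    out <- do.call(rbind, rows)
    data.frame(exon_id = rownames(m), out, row.names = NULL)
}

#' Rank exons by the timing of their splicing switch
#'
#' Keeps reliable fits only and orders them by ascending switch time `m`,
#' breaking ties by exon id so the ranking is deterministic.
#'
#' @param fits data.frame from [fitSigmoidMatrix()].
#' @return the filtered fits, ordered; a `rank` column is prepended.
#' @export
rankBySwitchTime <- function(fits) {
    stopifnot(all(c("exon_id", "m", "reliable") %in% names(fits)))
    keep <- fits[fits$reliable %in% TRUE, , drop = FALSE]
    keep <- keep[order(keep$m, keep$exon_id), , drop = FALSE]
    data.frame(rank = seq_len(nrow(keep)), keep, row.names = NULL)
}
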