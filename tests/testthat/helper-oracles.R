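# Independent oracles used to cross-check package computations. These stay
# deliberately naive: exact enumeration and brute-force loops, no shared code
# with the implementation.

# two-sided Fisher p for the 2x2 table rbind(c(a, c), c(b, d)) by exhaustive
# enumeration over all tables with the same margins: sum the point
# probabilities of every table no more probable than the observed one
fisherEnumOracle <- function(a, b, c, d) {
    R1 <- a + c; C1 <- a + b; N <- a + b + c + d
    if (R1 == 0 || C1 == 0 || R1 == N || C1 == N) return(1)
    js <- max(0, C1 - (N - R1)):min(R1, C1)
    probs <- stats::dhyper(js, R1, N - R1, C1)
    pobs <- stats::dhyper(a, R1, N - R1, C1)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# upper-tail hypergeometric by explicit binomial-coefficient sums
hyperEnumOracle <- function(k, K, n, N) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# beta log-likelihood for a no-intercept logit-link fit; grid-search maximum
betaGridOracle <- function(y, X, beta_grids, logphi_grid) {
    grid <- do.call(expand.grid, c(beta_grids, list(lp = logphi_grid)))
    t <- ncol(X)
    best <- -Inf
    bestPar <- NULL
    for (i in seq_len(nrow(grid))) {
        b <- as.numeric(grid[i, seq_len(t)])
        mu <- stats::plogis(drop(X %*% b))
        phi <- exp(grid$lp[i])
        ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
        if (ll > best) {
            best <- ll
            bestPar <- c(b, grid$lp[i])
        }
    }
    list(logLik = best, par = bestPar)
}

# adjacency by a naive double loop
naiveAdjacency <- function(m, power = 3) {
    n <- nrow(m)
    a <- matrix(0, n, n)
    for (u in seq_len(n)) for (v in seq_len(n))
        a[u, v] <- abs(stats::cor(m[u, ], m[v, ]))^power
    diag(a) <- 1
    a
}

# hand step-up BH: q_i = min over j with p_(j) >= p_i of n * p_(j) / j
bhHandOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    adj <- pmin(n * p[o] / seq_len(n), 1)
    adj <- rev(cummin(rev(adj)))
    q[o] <- adj
    q
}

refStages <- function() c("E14.5", "E16.5", "P0", "P4", "P7",
                          "P15", "P30", "4mo", "21mo")

# planted two-module fixture: step-up at P0 vs step-up at P7, each module
# with mirrored (anti-correlated) partners, reflected Gaussian noise
makeSteppedPsi <- function(n_per_module = 60, noise_sd = 0.05, seed = 1) {
    stages <- refStages()
    t <- toLog10Pcdays(stages)
    set.seed(seed)
    stepAt <- function(cut) as.numeric(t >= toLog10Pcdays(cut) - 1e-9)
    base <- list(early = stepAt("P0"), late = stepAt("P7"))
    rows <- list()
    truth <- character()
    for (mod in names(base)) {
        for (i in seq_len(n_per_module)) {
            a <- runif(1, 0.05, 0.2)
            k <- runif(1, 0.8, 0.95)
            prof <- a + (k - a) * base[[mod]]
            if (i > n_per_module / 2) prof <- a + k - prof  # mirrored partner
            rows[[paste0(mod, i)]] <- prof
            truth <- c(truth, mod)
        }
    }
    m <- do.call(rbind, rows)
    m <- m + rnorm(length(m), 0, noise_sd)
    m[m < 0] <- -m[m < 0]
    m[m > 1] <- 2 - m[m > 1]
    colnames(m) <- stages
    list(psi = m, truth = truth)
}

# two modules whose (noise-free) eigenexons correlate exactly at `rho`
makeCorrelatedModules <- function(rho = 0.8, n_per_module = 35, seed = 2) {
    stages <- refStages()
    nT <- length(stages)
    set.seed(seed)
    z1 <- scale(sigmoidPsi(toLog10Pcdays(stages), 0, 1, 12, 1.3))[, 1]
    z1 <- z1 / sqrt(sum(z1^2))
    raw <- rnorm(nT)
    zp <- raw - sum(raw * z1) * z1
    zp <- zp - mean(zp)
    zp <- zp - sum(zp * z1) * z1          # orthogonal to z1 and centered
    zp <- zp / sqrt(sum(zp^2))
    z2 <- rho * z1 + sqrt(1 - rho^2) * zp
    mk <- function(z) {
        # majority-positive amplitudes keep the eigenexon orientation
        # aligned with z, so the planted eigenexon correlation is +rho
        t(vapply(seq_len(n_per_module), function(i) {
            amp <- runif(1, 0.1, 0.3) *
                sample(c(-1, 1), 1, prob = c(0.3, 0.7))
            0.5 + amp * z / max(abs(z))
        }, numeric(nT)))
    }
    m <- rbind(mk(z1), mk(z2))
    rownames(m) <- sprintf("ex%03d", seq_len(2 * n_per_module))
    colnames(m) <- stages
    list(psi = m, truth = rep(c("A", "B"), each = n_per_module))
}
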