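#' Configuration for the strain deconvolution engine
#'
#' @param K Maximum number of inferred strains (the "expected number of
#'   strains" the user supplies; the engine may return fewer after pruning).
#' @param eps Error floor: inferred per-site success probabilities are kept
#'   inside \[eps, 1 - eps\] so a finite likelihood tolerates sequencing
#'   noise and model misfit.
#' @param lambda Genotype-discreteness penalty weight (a Beta(a, a), a < 1
#'   log-prior on each genotype entry, pushing entries toward 0/1; in units
#'   of read counts).
#' @param n_rounds Dictionary-building rounds (abundance refit + residual
#'   strain extraction + pruning).
#' @param gain_min_per_site Minimum per-site log-likelihood gain for a
#'   residual-extracted strain to enter the dictionary.
#' @param replace_cost_per_site Per-site log-likelihood cost below which a
#'   narrowly supported strain is judged redundant — i.e. its samples are
#'   explained nearly as well by shared strains plus freshly extracted
#'   residual strains — and removed from the dictionary.
#' @param shared_neff Effective-sample-count threshold above which a strain
#'   counts as "shared" (kept out of the hold-out replacement test).
#' @param seed_depth_frac Only samples whose mean coverage is at least this
#'   fraction of the best-covered sample seed the initial dictionary (their
#'   rounded profiles are least noise-contaminated).
#' @param noise_margin Number of standard deviations above the expected
#'   pure-noise extraction gain a candidate must clear to be admitted;
#'   0 disables the noise envelope.
#' @param novelty_threshold Candidate strains at or above this Jaccard
#'   similarity to an existing dictionary strain are not added.
#' @param consolidate_threshold Dictionary strains at or above this mutual
#'   Jaccard similarity are treated as twin representatives of one strain
#'   and merged between rounds.
#' @param prune_min_abundance Strains whose largest within-sample abundance
#'   never reaches this value are dropped between rounds.
#' @param max_iter Iteration cap for the joint (polish) EM phase.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed recorded in the result (the engine is
#'   deterministic given its inputs).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(K = 300, eps = 0.01, lambda = 5, n_rounds = 4,
                       gain_min_per_site = 0.025,
                       replace_cost_per_site = 0.15,
                       shared_neff = 6,
                       novelty_threshold = 0.95,
                       consolidate_threshold = 1,
                       prune_min_abundance = 0.02,
                       seed_depth_frac = 0.5, noise_margin = 2,
                       max_iter = 1000,
                       tol = 1e-6, seed = 1) {
  assert_count(K, "K")
  if (eps <= 0 || eps >= 0.5) stop_invalid("eps must be in (0, 0.5)")
  structure(list(K = as.integer(K), eps = eps, lambda = lambda,
                 n_rounds = as.integer(n_rounds),
                 gain_min_per_site = gain_min_per_site,
                 replace_cost_per_site = replace_cost_per_site,
                 shared_neff = shared_neff,
                 novelty_threshold = novelty_threshold,
                 consolidate_threshold = consolidate_threshold,
                 prune_min_abundance = prune_min_abundance,
                 seed_depth_frac = seed_depth_frac,
                 noise_margin = noise_margin,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Construct / validate an inference result
#'
#' @param genotypes K x sites matrix of fractional genotypes in \[0, 1\] with
#'   unique strain row names.
#' @param abundances Samples x K abundance matrix, rows summing to 1 within
#'   1e-6, columns named as the genotype rows.
#' @param per_sample_error Optional named per-sample reconstruction errors.
#' @param converged,objective,seed Optional fit metadata.
#' @return An object of class `strain_inference`.
#' @export
strain_inference <- function(genotypes, abundances, per_sample_error = NULL,
                             converged = NA, objective = NULL, seed = NULL) {
  genotypes <- as.matrix(genotypes)
  abundances <- as.matrix(abundances)
  if (any(genotypes < 0) || any(genotypes > 1)) {
    stop_invalid("genotype entries must lie in [0, 1]")
  }
  if (nrow(genotypes) != ncol(abundances)) {
    stop_invalid("strain count differs between genotypes (", nrow(genotypes),
                 ") and abundances (", ncol(abundances), ")")
  }
  bad <- which(abs(rowSums(abundances) - 1) > 1e-6)
  if (length(bad)) {
    stop_invalid("abundance row(s) not summing to 1: ",
                 paste(utils::head(rownames(abundances)[bad] %||% bad, 3),
                       collapse = ", "))
  }
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("inferred_%03d", seq_len(nrow(genotypes)))
  }
  colnames(abundances) <- rownames(genotypes)
  structure(list(genotypes = genotypes, abundances = abundances,
                 per_sample_error = per_sample_error, converged = converged,
                 objective = objective, seed = seed),
            class = "strain_inference")
}

#' @export
print.strain_inference <- function(x, ...) {
  cat("strain_inference:", nrow(x$genotypes), "strains,",
      nrow(x$abundances), "samples,", ncol(x$genotypes), "sites")
  if (!is.na(x$converged)) cat(";", if (x$converged) "converged" else
    "NOT converged")
  cat("\n")
  invisible(x)
}

# Binomial log-likelihood of one sample under mixture probabilities.
sample_loglik <- function(a, b, p) {
  p <- clip(p, 1e-12, 1 - 1e-12)
  sum(a * log(p) + b * log1p(-p))
}

# Exact per-sample abundance MLE over the probability simplex by active-set
# projected Newton with column generation. Given fixed genotype success
# probabilities the per-sample log-likelihood is concave in the abundances,
# so the KKT point found here is the global per-sample optimum. Plain
# abundance EM is avoided deliberately: with nearly collinear strains its
# convergence is too slow for allocation decisions to be trusted.
solve_abundance <- function(a, b, Gt, logG = NULL, log1G = NULL,
                            max_supp = 40, kkt_tol_rel = 1e-9,
                            init = NULL) {
  K <- nrow(Gt)
  if (K == 1) return(1)
  if (!is.null(init) && any(init > 1e-8)) {
    supp <- which(init > 1e-8)
    pi_s <- init[supp] / sum(init[supp])
  } else {
    if (is.null(logG)) { logG <- log(Gt); log1G <- log1p(-Gt) }
    ll_pure <- drop(logG %*% a + log1G %*% b)
    supp <- which.max(ll_pure)
    pi_s <- 1
  }
  total <- sum(a) + sum(b)
  for (outer in seq_len(60)) {
    G_s <- Gt[supp, , drop = FALSE]
    for (nit in seq_len(60)) {
      p <- clip(drop(pi_s %*% G_s), 1e-12, 1 - 1e-12)
      ll <- sum(a * log(p) + b * log1p(-p))
      u <- a / p - b / (1 - p)
      w <- a / p^2 + b / (1 - p)^2
      grad <- drop(G_s %*% u)
      Gw <- G_s * rep(w, each = nrow(G_s))
      H <- Gw %*% t(G_s)
      diag(H) <- diag(H) + 1e-8 * mean(diag(H))
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(Hi)) break
      Hg <- Hi %*% grad
      H1 <- Hi %*% rep(1, length(supp))
      nu <- sum(Hg) / sum(H1)
      d <- drop(Hg - nu * H1)
      if (max(abs(d)) < 1e-12) break
      neg <- d < 0
      t_step <- if (any(neg)) min(1, 0.999 * min(-pi_s[neg] / d[neg])) else 1
      lln <- -Inf
      repeat {
        pin <- pi_s + t_step * d
        pn <- clip(drop(pin %*% G_s), 1e-12, 1 - 1e-12)
        lln <- sum(a * log(pn) + b * log1p(-pn))
        if (lln >= ll - 1e-12 || t_step < 1e-10) break
        t_step <- t_step / 2
      }
      if (lln < ll && t_step < 1e-10) break
      pi_s <- pin
      gone <- pi_s < 1e-12
      if (any(gone)) {
        supp <- supp[!gone]
        pi_s <- pi_s[!gone] / sum(pi_s[!gone])
        G_s <- Gt[supp, , drop = FALSE]
      }
      if (lln - ll < 1e-10 * abs(ll)) break
    }
    # simplex KKT check over the full dictionary; admit the worst violator
    p <- clip(drop(pi_s %*% Gt[supp, , drop = FALSE]), 1e-12, 1 - 1e-12)
    u <- a / p - b / (1 - p)
    grad_all <- drop(Gt %*% u)
    mu <- sum(pi_s * grad_all[supp])
    viol <- grad_all - mu
    viol[supp] <- -Inf
    ok <- which(viol > kkt_tol_rel * total)
    if (length(ok) == 0 || length(supp) >= max_supp) break
    add <- ok[order(-viol[ok])]
    add <- utils::head(add, min(3, max_supp - length(supp)))
    supp <- c(supp, add)
    w0 <- 1e-3 * length(add)
    pi_s <- c(pi_s * (1 - w0), rep(1e-3, length(add)))
  }
  out <- numeric(K)
  out[supp] <- pi_s
  out
}

# Per-strain, per-site binary genotype coordinate update given abundances:
# for each strain the likelihood is separable across sites, so both allele
# choices are evaluated exactly and the better one kept. Returns the updated
# success-probability matrix (entries eps / 1 - eps).
update_genotypes_binary <- function(A, B, Gt, Pi, eps) {
  K <- nrow(Gt); n <- nrow(A)
  P <- Pi %*% Gt
  flips <- 0
  for (k in seq_len(K)) {
    pik <- Pi[, k]
    if (sum(pik) < 1e-8) next
    P0 <- P - outer(pik, Gt[k, ])
    Plo <- clip(P0 + pik * eps, 1e-12, 1 - 1e-12)
    Phi <- clip(P0 + pik * (1 - eps), 1e-12, 1 - 1e-12)
    ll_lo <- colSums(A * log(Plo) + B * log1p(-Plo))
    ll_hi <- colSums(A * log(Phi) + B * log1p(-Phi))
    gnew <- ifelse(ll_hi > ll_lo, 1 - eps, eps)
    flips <- flips + sum(abs(gnew - Gt[k, ]) > 1e-9)
    P <- P0 + outer(pik, gnew)
    Gt[k, ] <- gnew
  }
  list(Gt = Gt, flips = flips)
}

# Expected (and spread of the) log-likelihood gain of the best single added
# binary strain when the current reconstruction is already correct, i.e. the
# gain obtainable by fitting pure binomial noise. Extraction candidates must
# beat this envelope, otherwise low-coverage samples spawn strains that
# memorize their own sampling noise. Exact per-site enumeration over the
# count distribution, maximized over the candidate mixing fractions.
null_extraction_gain <- function(d, phat,
                                 alphas = c(0.05, 0.1, 0.2, 0.3,
                                            0.5, 0.7, 0.9)) {
  phat <- clip(phat, 1e-9, 1 - 1e-9)
  best_mean <- 0; best_var <- 0
  for (al in alphas) {
    p1 <- clip((1 - al) * phat + al, 1e-12, 1 - 1e-12)
    p0 <- clip((1 - al) * phat, 1e-12, 1 - 1e-12)
    c1a <- log(p1 / phat); c1b <- log((1 - p1) / (1 - phat))
    c0a <- log(p0 / phat); c0b <- log((1 - p0) / (1 - phat))
    mean_al <- 0; var_al <- 0
    for (dval in unique(d)) {
      sel <- which(d == dval)
      avec <- 0:dval
      # P[s, a]: binomial mass of count a at site s
      lp <- outer(log(phat[sel]), avec) +
        outer(log1p(-phat[sel]), dval - avec) +
        matrix(lchoose(dval, avec), length(sel), dval + 1, byrow = TRUE)
      P <- exp(lp)
      L1 <- outer(c1a[sel], avec) + outer(c1b[sel], dval - avec)
      L0 <- outer(c0a[sel], avec) + outer(c0b[sel], dval - avec)
      g <- pmax(L1, L0)
      g[g < 0] <- 0
      m1 <- rowSums(P * g)
      m2 <- rowSums(P * g * g)
      mean_al <- mean_al + sum(m1)
      var_al <- var_al + sum(pmax(m2 - m1^2, 0))
    }
    if (mean_al > best_mean) { best_mean <- mean_al; best_var <- var_al }
  }
  c(mean = best_mean, sd = sqrt(best_var))
}

# Backward elimination of strains that do not pay for themselves: for each
# moderately used strain (ascending usage), tentatively remove it, re-solve
# the abundances of the samples that used it, and drop it permanently when
# the total log-likelihood cost is below `cost`. Heavily used strains are
# left alone (their cost is necessarily far above any sensible threshold).
backward_eliminate <- function(A, B, Gd, Pi, eps, cost, max_neff = 12) {
  repeat {
    K <- nrow(Gd)
    if (K <= 1) break
    Gt <- eps + (1 - 2 * eps) * Gd
    usage <- colSums(Pi)
    neff <- usage^2 / (colSums(Pi^2) + 1e-12)
    test_order <- order(usage)
    removed <- FALSE
    for (k in test_order) {
      if (neff[k] > max_neff) next
      users <- which(Pi[, k] > 0.005)
      if (length(users) == 0) next
      Gt_wo <- Gt[-k, , drop = FALSE]
      logG <- log(Gt_wo); log1G <- log1p(-Gt_wo)
      dll <- 0
      Pi_new_users <- matrix(0, length(users), K - 1)
      for (ui in seq_along(users)) {
        i <- users[ui]
        ll_with <- sample_loglik(A[i, ], B[i, ], drop(Pi[i, ] %*% Gt))
        init_wo <- Pi[i, -k]
        pi_wo <- solve_abundance(A[i, ], B[i, ], Gt_wo, logG, log1G,
                                 init = init_wo)
        Pi_new_users[ui, ] <- pi_wo
        dll <- dll + ll_with -
          sample_loglik(A[i, ], B[i, ], drop(pi_wo %*% Gt_wo))
        if (dll > cost) break
      }
      if (dll <= cost) {
        Gd <- Gd[-k, , drop = FALSE]
        Pi <- Pi[, -k, drop = FALSE]
        Pi[users[seq_len(nrow(Pi_new_users))], ] <- Pi_new_users
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  Pi <- Pi / rowSums(Pi)   # non-user rows lose the (< 0.005) dropped mass
  list(Gd = Gd, Pi = Pi)
}

# Exact abundance refit for all samples (rows of A/B); `warm` optionally
# provides per-sample starting supports from a previous solve.
solve_abundance_all <- function(A, B, Gt, warm = NULL) {
  if (nrow(Gt) == 1) return(matrix(1, nrow(A), 1))
  logG <- log(Gt); log1G <- log1p(-Gt)
  t(vapply(seq_len(nrow(A)), function(i) {
    solve_abundance(A[i, ], B[i, ], Gt, logG, log1G,
                    init = if (is.null(warm)) NULL else warm[i, ])
  }, numeric(nrow(Gt))))
}

# Best single additional binary strain for one sample: for each candidate
# mixing fraction, the per-site allele maximizing the binomial likelihood of
# (1 - alpha) * current + alpha * allele; returns the best genotype and its
# log-likelihood gain.
extract_residual_strain <- function(a, d, phat,
                                    alphas = c(0.05, 0.1, 0.2, 0.3,
                                               0.5, 0.7, 0.9)) {
  b <- d - a
  p0c <- clip(phat, 1e-12, 1 - 1e-12)
  ll0 <- sum(a * log(p0c) + b * log1p(-p0c))
  gain_of <- function(al, h) {
    p <- clip((1 - al) * phat + al * h, 1e-12, 1 - 1e-12)
    sum(a * log(p) + b * log1p(-p)) - ll0
  }
  best <- NULL; bestgain <- 0; bestal <- NA_real_
  for (al in alphas) {
    p1 <- clip((1 - al) * phat + al, 1e-12, 1 - 1e-12)
    p0 <- clip((1 - al) * phat, 1e-12, 1 - 1e-12)
    l1 <- a * log(p1) + b * log1p(-p1)
    l0 <- a * log(p0) + b * log1p(-p0)
    gain <- sum(pmax(l1, l0)) - ll0
    if (gain > bestgain) {
      bestgain <- gain; best <- as.integer(l1 > l0); bestal <- al
    }
  }
  if (is.null(best)) return(list(genotype = NULL, gain = 0))
  # refine: alternate a 1-D Newton step on the mixing fraction with exact
  # per-site allele re-selection
  al <- bestal
  for (it in 1:3) {
    delta <- best - phat
    p <- clip(phat + al * delta, 1e-12, 1 - 1e-12)
    g1 <- sum(delta * (a / p - b / (1 - p)))
    g2 <- -sum(delta^2 * (a / p^2 + b / (1 - p)^2))
    if (is.finite(g1) && is.finite(g2) && g2 < 0) {
      al <- clip(al - g1 / g2, 0.01, 0.99)
    }
    p1 <- clip((1 - al) * phat + al, 1e-12, 1 - 1e-12)
    p0 <- clip((1 - al) * phat, 1e-12, 1 - 1e-12)
    l1 <- a * log(p1) + b * log1p(-p1)
    l0 <- a * log(p0) + b * log1p(-p0)
    h_new <- as.integer(l1 > l0)
    if (identical(h_new, best)) { best <- h_new; break }
    best <- h_new
  }
  g_final <- gain_of(al, best)
  if (g_final > bestgain) bestgain <- g_final
  list(genotype = best, gain = bestgain)
}

#' Deconvolve strains from metagenotypes
#'
#' Jointly infers binary-leaning strain genotypes and per-sample strain
#' abundances from allele-count matrices under a binomial mixture model: the
#' alternate-allele count of sample i at site s is Binomial(depth,
#' clip(sum_k pi_ik g_ks, eps, 1 - eps)).
#'
#' The engine builds a genotype dictionary progressively. (1) Discretized
#' per-sample allele-fraction profiles seed the dictionary. (2) For several
#' rounds: every sample's abundances over the current dictionary are solved
#' exactly (the problem is concave given genotypes; an active-set projected
#' Newton solver finds each sample's global optimum); each sample is then
#' re-explained with its "private" strains held out and up to two novel
#' binary strains are extracted from the leftover signal; novel candidates
#' are admitted by likelihood gain; private strains whose samples are
#' explained nearly as well without them (redundant "blend" directions that
#' would otherwise soak up shared-strain abundance) are removed; strains
#' that never reach meaningful abundance are pruned. (3) A joint EM polish
#' under a genotype-discreteness penalty sharpens genotypes (the penalized
#' objective is non-increasing across iterations). (4) The final abundances
#' re-solve every sample's concave allocation exactly against the polished
#' genotypes. The result is deterministic for fixed inputs and
#' configuration.
#'
#' @param x A [metagenotype_set()] (or list of `metagenotype` objects).
#' @param config A [fit_config()]; `config$K` caps the dictionary size.
#' @return A [strain_inference()] with fractional genotypes, per-sample
#'   abundances, per-sample reconstruction errors, the polish-phase penalized
#'   objective trace in `$objective`, and a `converged` flag (a warning is
#'   emitted when the polish phase hits its iteration cap).
#' @export
fit_mixture <- function(x, config = fit_config()) {
  x <- as_metagenotype_set(x)
  stopifnot(inherits(config, "fit_config"))
  A <- x$alt; D <- x$ref + x$alt; B <- x$ref
  n <- nrow(A); S <- ncol(A)
  if (any(rowSums(D) == 0)) stop_invalid("sample(s) with zero total depth")
  eps <- config$eps; lambda <- config$lambda
  X <- A / D
  X[D == 0] <- 0
  gain_min <- config$gain_min_per_site * S

  # phase 1: dictionary seeded from discretized profiles of well-covered
  # samples only — the rounded profile of a shallow sample is dominated by
  # sampling noise and would enter as an uncorrectable noise replica
  meanD <- rowMeans(D)
  seed_rows <- meanD >= config$seed_depth_frac * max(meanD)
  if (!any(seed_rows)) seed_rows <- rep(TRUE, n)
  Gd <- unique((X[seed_rows, , drop = FALSE] >= 0.5) * 1)

  # phase 2: refit / extract / replace / prune rounds
  replace_cost <- config$replace_cost_per_site * S
  for (round in seq_len(config$n_rounds)) {
    Gt <- eps + (1 - 2 * eps) * Gd
    logG <- log(Gt); log1G <- log1p(-Gt)
    Pi <- solve_abundance_all(A, B, Gt)
    K <- nrow(Gd)
    # breadth of support: effective number of samples using each strain;
    # broadly used strains (the product strain, popular endogenous reps) are
    # "shared", narrowly used ones are candidates for replacement
    usage <- colSums(Pi)
    neff <- usage^2 / (colSums(Pi^2) + 1e-12)
    # "shared" strains anchor the hold-out refits: they must be broadly used
    # in absolute terms and comparable to the most broadly used strain, so
    # that moderately spread blend strains still face the replacement test
    shared <- neff > max(config$shared_neff, 0.5 * max(neff))
    # single-strain log-likelihood of every strain for every sample, used to
    # shortlist plausible explanatory strains for the hold-out refits
    LLpure <- logG %*% t(A) + log1G %*% t(B)
    cand <- NULL
    gains <- numeric(0)
    cand_holdout <- list()
    repl <- vector("list", n)
    lo_row <- log(eps); hi_row <- log(1 - eps)
    for (i in seq_len(n)) {
      ll_full <- sample_loglik(A[i, ], B[i, ], drop(Pi[i, ] %*% Gt))
      # hold out the narrowly supported strains this sample leans on,
      # explain the sample with the shared remainder, and peel up to three
      # novel binary strains from what is left over
      priv <- which(!shared & Pi[i, ] > 0.01)
      base <- union(which(shared), which(Pi[i, ] > 1e-6))
      extra <- setdiff(order(LLpure[, i], decreasing = TRUE), c(base, priv))
      keepk <- setdiff(union(base, utils::head(extra, 15)), priv)
      if (length(priv) > 0) {
        if (length(keepk) > 0) {
          Gsub <- Gt[keepk, , drop = FALSE]
          logGsub <- logG[keepk, , drop = FALSE]
          log1Gsub <- log1G[keepk, , drop = FALSE]
          pi_lo <- solve_abundance(A[i, ], B[i, ], Gsub, logGsub, log1Gsub)
          phat <- drop(pi_lo %*% Gsub)
        } else {
          # nothing shared to lean on: extract against an empty community
          Gsub <- matrix(eps, 0, S)
          logGsub <- matrix(0, 0, S); log1Gsub <- matrix(0, 0, S)
          phat <- rep(eps, S)
        }
        gain_min_i <- gain_min
        if (config$noise_margin > 0) {
          env <- null_extraction_gain(D[i, ], phat)
          gain_min_i <- max(gain_min,
                            env["mean"] + config$noise_margin * env["sd"])
        }
        for (pass in 1:3) {
          ex <- extract_residual_strain(A[i, ], D[i, ], phat)
          if (is.null(ex$genotype) || ex$gain <= gain_min_i) break
          cand <- rbind(cand, ex$genotype)
          gains <- c(gains, ex$gain)
          cand_holdout[[length(gains)]] <- priv
          Gsub <- rbind(Gsub, eps + (1 - 2 * eps) * ex$genotype)
          logGsub <- rbind(logGsub, ifelse(ex$genotype == 1, hi_row, lo_row))
          log1Gsub <- rbind(log1Gsub, ifelse(ex$genotype == 1, lo_row, hi_row))
          pi_lo <- solve_abundance(A[i, ], B[i, ], Gsub, logGsub, log1Gsub)
          phat <- drop(pi_lo %*% Gsub)
        }
        # if the hold-out explanation (shared strains + extracted novelties)
        # is nearly as good as the full one, the held-out strains are
        # redundant "blend" directions and are scheduled for removal
        ll_repl <- sample_loglik(A[i, ], B[i, ], phat)
        if (ll_full - ll_repl <= replace_cost) repl[[i]] <- priv
      } else if (length(priv) == 0) {
        # sample fully explained by shared strains: peel any leftover signal
        phat <- drop(Pi[i, ] %*% Gt)
        ex <- extract_residual_strain(A[i, ], D[i, ], phat)
        if (!is.null(ex$genotype) && ex$gain > gain_min) {
          ok <- TRUE
          if (config$noise_margin > 0) {
            env <- null_extraction_gain(D[i, ], phat)
            ok <- ex$gain > env["mean"] + config$noise_margin * env["sd"]
          }
          if (ok) {
            cand <- rbind(cand, ex$genotype)
            gains <- c(gains, ex$gain)
            cand_holdout[[length(gains)]] <- integer(0)
          }
        }
      }
    }
    n_added <- 0
    K0 <- nrow(Gd)
    if (!is.null(cand)) {
      ord <- order(-gains)   # admit highest-gain candidates first
      for (r in ord) {
        if (nrow(Gd) >= config$K) break
        # novelty is judged against the dictionary minus the candidate's own
        # held-out strains (which it may be about to replace)
        ref_rows <- setdiff(seq_len(nrow(Gd)),
                            cand_holdout[[r]] %||% integer(0))
        if (length(ref_rows) == 0 ||
            max(jaccard_cross(cand[r, , drop = FALSE],
                              Gd[ref_rows, , drop = FALSE])) <
              config$novelty_threshold) {
          Gd <- rbind(Gd, cand[r, ])
          n_added <- n_added + 1
        }
      }
    }
    drop_idx <- unique(unlist(repl))   # row indices in the pre-admission Gd
    drop_idx <- drop_idx[drop_idx <= K0]
    if (length(drop_idx) >= nrow(Gd)) drop_idx <- integer(0)
    if (length(drop_idx)) Gd <- Gd[-drop_idx, , drop = FALSE]
    # sharpen: alternate exact abundance solves with exact binary per-site
    # genotype updates, which strips residual cross-contamination (e.g.
    # product-strain alleles absorbed into endogenous representatives)
    Gt <- eps + (1 - 2 * eps) * Gd
    Pi_warm <- NULL
    for (alt in 1:8) {
      Pi <- solve_abundance_all(A, B, Gt, warm = Pi_warm)
      up <- update_genotypes_binary(A, B, Gt, Pi, eps)
      Gt <- up$Gt
      Pi_warm <- Pi
      if (up$flips == 0) break
    }
    Gd <- (Gt >= 0.5) * 1
    dup <- duplicated(Gd)
    if (any(dup)) Gd <- Gd[!dup, , drop = FALSE]
    Gt <- eps + (1 - 2 * eps) * Gd
    Pi <- solve_abundance_all(A, B, Gt)
    keep <- apply(Pi, 2, max) > config$prune_min_abundance
    if (sum(keep) >= 1) {
      Gd <- Gd[keep, , drop = FALSE]
      Pi <- Pi[, keep, drop = FALSE]
    }
    # consolidate: twin representatives of one true strain (far more similar
    # than two distinct strains ever are) are merged — the broadly used twin
    # survives — so the sharpening pass re-estimates a single consensus
    # genotype from all the twins' user samples
    repeat {
      if (nrow(Gd) < 2) break
      Jd <- jaccard_cross(Gd, Gd)
      diag(Jd) <- 0
      hits <- which(Jd >= config$consolidate_threshold, arr.ind = TRUE)
      if (nrow(hits) == 0) break
      usage <- colSums(Pi)
      pair <- as.integer(hits[1, ])
      wi <- if (usage[pair[1]] >= usage[pair[2]]) 1L else 2L
      winner <- pair[wi]; loser <- pair[3L - wi]
      Pi[, winner] <- Pi[, winner] + Pi[, loser]
      Gd <- Gd[-loser, , drop = FALSE]
      Pi <- Pi[, -loser, drop = FALSE]
    }
    # backward elimination: a strain must justify its existence — removing
    # it and re-solving its user samples must cost at least replace_cost in
    # log-likelihood — otherwise it is a redundant partial blend of others
    be <- backward_eliminate(A, B, Gd, Pi, eps, replace_cost)
    n_elim <- nrow(Gd) - nrow(be$Gd)
    Gd <- be$Gd; Pi <- be$Pi
    if (n_added == 0 && length(drop_idx) == 0 && n_elim == 0) break
  }

  # phase 3: joint penalized EM polish
  Kp <- nrow(Gd)
  Gt <- eps + (1 - 2 * eps) * Gd
  if (ncol(Pi) != Kp) Pi <- solve_abundance_all(A, B, Gt)
  obj <- Inf
  trace <- numeric(0)
  converged <- FALSE
  lo <- matrix(eps, Kp, S); hi <- matrix(1 - eps, Kp, S)
  for (it in seq_len(config$max_iter)) {
    P <- clip(Pi %*% Gt, 1e-12, 1 - 1e-12)
    newobj <- -(sum(A * log(P) + B * log1p(-P))) +
      lambda * sum(log(Gt) + log1p(-Gt))
    trace <- c(trace, newobj)
    if (is.finite(obj) && abs(obj - newobj) <= config$tol * abs(obj)) {
      converged <- TRUE
      break
    }
    obj <- newobj
    RA <- A / P; RB <- B / (1 - P)
    Pi_new <- Pi * (RA %*% t(Gt) + RB %*% t(1 - Gt))
    Pi_new <- Pi_new / rowSums(Pi_new)
    Na <- Gt * (t(Pi) %*% RA)
    Nr <- (1 - Gt) * (t(Pi) %*% RB)
    qf <- function(g) (Na - lambda) * log(g) + (Nr - lambda) * log1p(-g)
    gint <- clip((Na - lambda) / (Na + Nr - 2 * lambda), eps, 1 - eps)
    gint[!is.finite(gint)] <- 0.5
    fi <- qf(gint); fl <- qf(lo); fh <- qf(hi)
    Gt_new <- gint
    Gt_new[fl >= fi & fl >= fh] <- eps
    Gt_new[fh > fi & fh > fl] <- 1 - eps
    Pi <- Pi_new; Gt <- Gt_new
  }
  if (!converged) {
    warning("joint EM phase reached max_iter without meeting tolerance; ",
            "returning best-so-far fit")
  }

  # phase 4: final abundance refit (exact per-sample global optimum)
  Ab <- solve_abundance_all(A, B, Gt)
  Geno <- clip((Gt - eps) / (1 - 2 * eps), 0, 1)
  rownames(Geno) <- sprintf("inferred_%03d", seq_len(nrow(Geno)))
  rownames(Ab) <- x$sample_ids
  res <- strain_inference(Geno, Ab, converged = converged,
                          objective = trace, seed = config$seed)
  res$per_sample_error <- reconstruction_error(x, res)
  res
}

#' Metagenotype reconstruction error
#'
#' Mean absolute difference, over covered sites, between a sample's observed
#' alternate-allele fraction and the alternate fraction reconstructed from
#' the inferred strains (abundance-weighted fractional genotypes). Depth-
#' unweighted; a value in \[0, 1\].
#'
#' @param x A `metagenotype` (single sample) or `metagenotype_set`.
#' @param result A `strain_inference` whose samples align with `x`.
#' @return A single error for a `metagenotype`, otherwise a named vector.
#' @export
reconstruction_error <- function(x, result) {
  stopifnot(inherits(result, "strain_inference"))
  one <- inherits(x, "metagenotype")
  x <- as_metagenotype_set(x)
  D <- x$ref + x$alt
  if (any(rowSums(D > 0) == 0)) stop_invalid("sample with zero depth everywhere")
  recon <- result$abundances %*% result$genotypes
  if (ncol(recon) != ncol(x$alt)) stop_invalid("site counts differ")
  err <- vapply(seq_len(nrow(x$alt)), function(i) {
    cov <- D[i, ] > 0
    mean(abs(x$alt[i, cov] / D[i, cov] - recon[i, cov]))
  }, numeric(1))
  names(err) <- x$sample_ids
  if (one) unname(err[1]) else err
}

#' Write or load inference tables
#'
#' `write_inference` emits three TSVs into `dir`: `inferred_genotypes.tsv`
#' (strain x site, fractional), `inferred_abundances.tsv` (sample x strain)
#' and `sample_errors.tsv`. `load_external_inference` reads the two former
#' tables — ours or a third-party tool's, in the same layout — validates
#' them, and returns a `strain_inference`; abundance rows are renormalized
#' when within 1e-3 of 1 and rejected otherwise.
#'
#' @param result A `strain_inference`.
#' @param dir Output directory (created if needed).
#' @export
write_inference <- function(result, dir) {
  stopifnot(inherits(result, "strain_inference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(result$genotypes,
                      file.path(dir, "inferred_genotypes.tsv"))
  ab <- data.frame(sample_id = rownames(result$abundances),
                   result$abundances, check.names = FALSE)
  utils::write.table(ab, file.path(dir, "inferred_abundances.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$per_sample_error)) {
    utils::write.table(
      data.frame(sample_id = names(result$per_sample_error),
                 error = unname(result$per_sample_error)),
      file.path(dir, "sample_errors.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_inference
#' @param genotype_table,abundance_table Paths to the two TSV tables.
#' @export
load_external_inference <- function(genotype_table, abundance_table) {
  G <- read_genotypes_tsv(genotype_table)
  if (any(G < 0) || any(G > 1)) {
    bad <- rownames(G)[which(rowSums(G < 0 | G > 1) > 0)[1]]
    stop_invalid("genotype entries outside [0, 1] in strain ", bad)
  }
  df <- utils::read.delim(abundance_table, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "sample_id") stop_invalid("first column must be sample_id")
  Ab <- as.matrix(df[, -1, drop = FALSE])
  rownames(Ab) <- df$sample_id
  if (!setequal(colnames(Ab), rownames(G))) {
    stop_invalid("strain ids differ between genotype and abundance tables")
  }
  Ab <- Ab[, rownames(G), drop = FALSE]
  rs <- rowSums(Ab)
  off <- which(abs(rs - 1) > 1e-3)
  if (length(off)) {
    stop_invalid("abundance row for sample '", rownames(Ab)[off[1]],
                 "' sums to ", signif(rs[off[1]], 4), ", not 1")
  }
  Ab <- Ab / rs
  strain_inference(G, Ab)
}
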