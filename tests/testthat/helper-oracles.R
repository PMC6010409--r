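# Independent oracle implementations used to cross-check the package.
# These deliberately use different primitives (base-R table()/sample())
# from the C++ core they validate.

# Neutral transmission oracle: model 1 with alpha = 1, v = 0, p_att = 1 is
# an unbiased sample-from-demonstrators drift process. Plain R rewrite.
oracle_neutral_sim <- function(N_p, N_s, mu, N_T, years, rep_probs,
                               mortality = 0.4) {
  sizes <- sample.int(length(rep_probs), N_p, replace = TRUE,
                      prob = rep_probs)
  reps <- lapply(sizes, function(r) sample.int(N_s, r))
  for (y in seq_len(years)) {
    dying <- runif(N_p) < mortality
    surv <- which(!dying)
    if (length(surv) == 0) stop("all died")
    for (i in which(dying)) {
      r_m <- sample.int(length(rep_probs), 1, prob = rep_probs)
      dem <- surv[sample.int(length(surv), min(N_T, length(surv)))]
      tab <- table(unlist(reps[dem]))
      types <- as.integer(names(tab))
      wts <- as.numeric(tab)
      avail <- seq_along(types)
      new_rep <- integer(0)
      # successive weighted draws without replacement from the memory
      while (length(new_rep) < r_m && length(avail) > 0) {
        pos <- if (length(avail) == 1) avail
               else sample(avail, 1, prob = wts[avail])
        avail <- setdiff(avail, pos)
        x <- types[pos]
        if (runif(1) < mu) {
          repeat {
            x2 <- sample.int(N_s, 1)
            if (x2 != x && !(x2 %in% new_rep)) { x <- x2; break }
          }
        }
        if (!(x %in% new_rep)) new_rep <- c(new_rep, x)
      }
      # unfilled slots can only innovate, with probability mu each
      for (s in seq_len(r_m - length(new_rep))) {
        if (runif(1) < mu) {
          repeat {
            x <- sample.int(N_s, 1)
            if (!(x %in% new_rep)) { new_rep <- c(new_rep, x); break }
          }
        }
      }
      reps[[i]] <- new_rep
    }
  }
  reps
}

# singer-count spectrum of a list of repertoires, binned for chi-square
# comparisons: number of types sung by 1, 2, 3, 4, 5+ individuals
spectrum_bins <- function(reps) {
  k <- table(unlist(reps))
  counts <- c(sum(k == 1), sum(k == 2), sum(k == 3), sum(k == 4),
              sum(k >= 5))
  names(counts) <- c("1", "2", "3", "4", "5+")
  counts
}

# exhaustive Plackett-Luce enumeration: probability that each item is the
# one left unselected (= removed) under successive weighted sampling
oracle_removal_probs <- function(w) {
  n <- length(w)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  probs <- numeric(n)
  for (ord in perms(seq_len(n))) {
    pr <- 1
    rem <- w
    idx <- seq_len(n)
    for (j in ord[-n]) {
      pos <- match(j, idx)
      pr <- pr * rem[pos] / sum(rem)
      rem <- rem[-pos]; idx <- idx[-pos]
    }
    probs[ord[n]] <- probs[ord[n]] + pr
  }
  probs
}

# naive O(n^3) average-linkage clustering; returns the cophenetic matrix
oracle_upgma_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  while (sum(active) > 1) {
    ia <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(ia)) for (b in seq_len(a - 1)) {
      i <- ia[a]; j <- ia[b]
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (x in clusters[[i]]) for (y in clusters[[j]]) {
      coph[x, y] <- bestd; coph[y, x] <- bestd
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active[j] <- FALSE
  }
  coph
}

# naive stratified Mantel: Pearson r over lower-triangle entries and a
# one-sided permutation p permuting items within strata only
oracle_mantel <- function(D1, D2, strata = NULL, n_perm = 499) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  lt <- lower.tri(D1)
  r_obs <- cor(D1[lt], D2[lt])
  n <- nrow(D1)
  if (is.null(strata)) strata <- rep(1, n)
  hits <- 0
  for (b in seq_len(n_perm)) {
    perm <- seq_len(n)
    for (g in unique(strata)) {
      idx <- which(strata == g)
      perm[idx] <- idx[sample.int(length(idx))]
    }
    Dp <- D2[perm, perm]
    if (cor(D1[lt], Dp[lt]) >= r_obs) hits <- hits + 1
  }
  list(r = r_obs, p = (hits + 1) / (n_perm + 1))
}

# mean Jaccard similarity among within- vs between-population pairs
sharing_contrast <- function(sample) {
  n <- nrow(sample)
  J <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    J[i, j] <- jaccard(sample$syllables[[i]], sample$syllables[[j]])
  same <- outer(sample$population, sample$population, "==")
  ut <- upper.tri(J)
  c(within = mean(J[ut & same]), between = mean(J[ut & !same]))
}

# block-structured dissimilarity matrix with k planted clusters
planted_dissim <- function(k, per, within = 0.1, between = 1, noise = 0.02) {
  n <- k * per
  lab <- rep(seq_len(k), each = per)
  D <- matrix(between, n, n)
  for (g in seq_len(k)) D[lab == g, lab == g] <- within
  D <- D + matrix(abs(rnorm(n * n, 0, noise)), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  list(D = D, labels = lab)
}
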