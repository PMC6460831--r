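# Independent slow-path oracles used to cross-check the package's
# optimized implementations. These deliberately share no code with the
# package internals: statistics come from stats::chisq.test on explicit
# matrices, partitions from plain data-frame splitting.

# Pearson statistic of a matrix, zero rows/columns dropped first (they
# contribute nothing); NA-free even for degenerate inputs.
oracle_chi2 <- function(m) {
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(0)
  unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic)
}

oracle_p_2x2 <- function(m) {
  if (any(colSums(m) == 0) || any(rowSums(m) == 0)) return(1)
  unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$p.value)
}

# Merge loop on an explicit count matrix: scores every candidate merge by
# building the merged matrix and calling chisq.test; same selection and
# stopping semantics as the package (max statistic, smallest pair on
# float-tolerance ties, local 2x2 test at alpha).
oracle_compress <- function(counts, ordinal, alpha) {
  groups <- as.list(seq_len(ncol(counts)))
  repeat {
    r <- ncol(counts)
    if (r < 2) break
    pairs <- if (ordinal) {
      cbind(seq_len(r - 1), seq_len(r - 1) + 1L)
    } else {
      p <- t(utils::combn(r, 2))
      p[order(p[, 1], p[, 2]), , drop = FALSE]
    }
    stats <- apply(pairs, 1, function(pr) {
      m <- counts
      m[, pr[1]] <- m[, pr[1]] + m[, pr[2]]
      oracle_chi2(m[, -pr[2], drop = FALSE])
    })
    mx <- max(stats)
    best <- which(stats >= mx - 1e-9 * max(1, abs(mx)))[1]
    i <- pairs[best, 1]; j <- pairs[best, 2]
    if (oracle_p_2x2(counts[, c(i, j), drop = FALSE]) < alpha) break
    counts[, i] <- counts[, i] + counts[, j]
    groups[[i]] <- c(groups[[i]], groups[[j]])
    counts <- counts[, -j, drop = FALSE]
    groups[j] <- NULL
  }
  list(counts = counts, groups = groups)
}

oracle_entropy <- function(pos, neg) {
  p <- c(pos, neg) / (pos + neg)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# ROC AUC as the tie-corrected Mann-Whitney statistic over all
# positive-negative score pairs.
oracle_auc_roc <- function(scores, labels) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels == "negative"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# PR AUC by explicit threshold enumeration: walk the distinct scores from
# high to low, record achievable (TP, FP) points, insert every
# intermediate integer TP with FP on the connecting line, then trapezoid.
oracle_auc_pr <- function(scores, labels) {
  npos <- sum(labels == "positive")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    c(tp = sum(scores >= t & labels == "positive"),
      fp = sum(scores >= t & labels == "negative"))
  }, numeric(2)))
  pts <- rbind(c(0, 0), pts)
  dens <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    k <- b[1] - a[1]
    if (k >= 2) {
      x <- seq_len(k - 1)
      dens[[length(dens) + 1]] <-
        cbind(a[1] + x, a[2] + (b[2] - a[2]) / k * x)
    }
    dens[[length(dens) + 1]] <- rbind(b)
  }
  d <- do.call(rbind, dens)
  d <- d[d[, 1] > 0, , drop = FALSE]
  rec <- d[, 1] / npos
  prec <- d[, 1] / (d[, 1] + d[, 2])
  rec <- c(0, rec)
  prec <- c(prec[1], prec)
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

# Plain-loop feature introduction on a data frame, using oracle_compress
# per cell and the direct entropy formulas; same selection semantics.
oracle_introduce <- function(df, specs, alpha) {
  n <- nrow(df)
  lab <- df$label
  cells <- list(rep(TRUE, n))   # logical row masks
  remaining <- specs$id
  introduced <- character(0)
  repeat {
    cand <- list()
    for (f in remaining) {
      spec <- specs[specs$id == f, ]
      dom <- spec$domain[[1]]
      per_cell <- lapply(cells, function(mask) {
        cnt <- sapply(dom, function(v) {
          c(sum(df[[f]][mask] == v & lab[mask] == "positive"),
            sum(df[[f]][mask] == v & lab[mask] == "negative"))
        })
        oracle_compress(matrix(cnt, nrow = 2), spec$kind == "ordinal", alpha)
      })
      if (!any(vapply(per_cell, function(x) length(x$groups) >= 2, logical(1)))) next
      sizes <- numeric(0); gain <- 0
      for (ci in seq_along(cells)) {
        mask <- cells[[ci]]
        np <- sum(lab[mask] == "positive"); nn <- sum(mask) - np
        if (np + nn == 0) next
        gain <- gain + (np + nn) / n * oracle_entropy(np, nn)
        for (g in per_cell[[ci]]$groups) {
          in_g <- mask & df[[f]] %in% dom[g]
          gp <- sum(lab[in_g] == "positive"); gn <- sum(in_g) - gp
          sizes <- c(sizes, gp + gn)
          if (gp + gn > 0) gain <- gain - (gp + gn) / n * oracle_entropy(gp, gn)
        }
      }
      pos_sizes <- sizes[sizes > 0]
      if (length(pos_sizes) < 2) next
      w <- pos_sizes / sum(pos_sizes)
      cand[[f]] <- list(gain = gain, ratio = gain / (-sum(w * log2(w))),
                        per_cell = per_cell, dom = dom)
    }
    if (length(cand) == 0) break
    gains <- vapply(cand, `[[`, numeric(1), "gain")
    elig <- names(cand)[gains >= mean(gains)]
    elig <- elig[order(match(elig, specs$id))]
    ratios <- vapply(cand[elig], `[[`, numeric(1), "ratio")
    mx <- max(ratios)
    chosen <- elig[which(ratios >= mx - 1e-9 * max(1, abs(mx)))[1]]
    new_cells <- list()
    for (ci in seq_along(cells)) {
      g <- cand[[chosen]]$per_cell[[ci]]$groups
      if (length(g) < 2) {
        new_cells[[length(new_cells) + 1]] <- cells[[ci]]
      } else {
        for (grp in g) {
          new_cells[[length(new_cells) + 1]] <-
            cells[[ci]] & df[[chosen]] %in% cand[[chosen]]$dom[grp]
        }
      }
    }
    cells <- new_cells
    introduced <- c(introduced, chosen)
    remaining <- setdiff(remaining, chosen)
    if (length(remaining) == 0) break
  }
  list(features = introduced,
       cell_counts = t(vapply(cells, function(mask) {
         c(sum(lab[mask] == "positive"), sum(lab[mask] == "negative"))
       }, numeric(2))))
}

random_window <- function(n, len = 11) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
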