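#' Build a two-row contingency table
#'
#' A `chi_table` holds class-by-status counts for one feature: row 1 counts
#' positive samples, row 2 negative samples, and each column is a status
#' group (a set of original status values such as bases or dinucleotide
#' counts). Counts may be non-integer because the balanced decision table
#' reweights negative counts by a real factor.
#'
#' @param positive,negative Numeric vectors of per-status counts, equal
#'   length, all non-negative.
#' @param groups List of character vectors naming the original status
#'   values in each column. Defaults to one singleton group per column.
#' @param ordinal Logical; `TRUE` when the statuses carry a total order
#'   (dinucleotide counts), in which case only adjacent columns may merge.
#' @return An object of class `chi_table`.
#' @examples
#' chi_table(c(30, 100, 120, 31), c(300, 400, 480, 298),
#'           groups = list("A", "C", "G", "T"))
#' @export
chi_table <- function(positive, negative, groups = NULL, ordinal = FALSE) {
  stopifnot(length(positive) == length(negative), length(positive) >= 1)
  if (any(positive < 0) || any(negative < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- as.list(paste0("s", seq_along(positive)))
  }
  stopifnot(length(groups) == length(positive))
  groups <- lapply(groups, as.character)
  counts <- rbind(positive = as.numeric(positive),
                  negative = as.numeric(negative))
  colnames(counts) <- vapply(groups, paste, character(1), collapse = "")
  structure(list(counts = counts, groups = groups, ordinal = isTRUE(ordinal)),
            class = "chi_table")
}

#' @export
print.chi_table <- function(x, ...) {
  kind <- if (x$ordinal) "ordinal" else "categorical"
  cat(sprintf("<chi_table: 2 x %d, %s>\n", ncol(x$counts), kind))
  print(round(x$counts, 2))
  invisible(x)
}

#' @rdname tidy.chidt_model
#' @export
tidy.chi_table <- function(x, ...) {
  tibble::tibble(
    group = vapply(x$groups, paste, character(1), collapse = ","),
    positive = x$counts[1, ],
    negative = x$counts[2, ]
  )
}

as_count_matrix <- function(x) {
  if (inherits(x, "chi_table")) x$counts else as.matrix(x)
}

#' Pearson chi-square statistic of a two-row table
#'
#' Plain Pearson statistic, no continuity correction; this is the statistic
#' used both for selecting merges during table compression and for the
#' plus-one decision rule on the fitted decision table. Cells whose
#' expected value is zero (all-zero row or column) contribute nothing.
#'
#' @param x A `chi_table` or a numeric matrix with two rows.
#' @return The statistic, a non-negative scalar.
#' @examples
#' chi2_stat(rbind(c(38, 12, 26, 12), c(184, 1026, 289, 188)))  # 109.2
#' @export
chi2_stat <- function(x) {
  m <- as_count_matrix(x)
  n <- sum(m)
  if (n <= 0) stop("degenerate table: all counts are zero", call. = FALSE)
  rs <- rowSums(m)
  cs <- colSums(m)
  e <- outer(rs, cs) / n
  ok <- e > 0
  sum((m[ok] - e[ok])^2 / e[ok])
}

#' Upper-tail chi-square probability
#'
#' @param stat Non-negative statistic.
#' @param df Degrees of freedom, at least 1. A 2 x r table has r - 1.
#' @param log10p If `TRUE`, return log10 of the p-value (computed in log
#'   space, so extreme statistics do not underflow; the per-position
#'   importance profile plots -log10 p values in the hundreds).
#' @return The p-value, or its log10.
#' @export
chi2_pvalue <- function(stat, df, log10p = FALSE) {
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stopifnot(all(stat >= 0))
  lp <- stats::pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Local merge test between two table columns
#'
#' P-value of the Pearson chi-square test on the local 2 x 2 table formed
#' by two columns. This is the stopping rule of the compression loop: a
#' candidate merge is kept only when the two columns are statistically
#' indistinguishable between classes (p at or above alpha). A column with
#' zero total carries no class information and merges freely (p = 1), which
#' guarantees that statuses unseen in a training cell are absorbed into
#' some group and every future sample still matches a rule.
#'
#' @param col_a,col_b Numeric 2-vectors (positive count, negative count).
#' @return A p-value in \[0, 1\].
#' @export
local_merge_test <- function(col_a, col_b) {
  stopifnot(length(col_a) == 2, length(col_b) == 2,
            all(col_a >= 0), all(col_b >= 0))
  if (sum(col_a) == 0 || sum(col_b) == 0) return(1)
  m <- cbind(col_a, col_b)
  if (any(rowSums(m) == 0)) return(1)  # one class absent: no discrimination
  chi2_pvalue(chi2_stat(m), df = 1)
}

merge_candidates <- function(r, ordinal) {
  if (r < 2) return(matrix(integer(0), ncol = 2))
  if (ordinal) {
    cbind(seq_len(r - 1), seq_len(r - 1) + 1L)
  } else {
    p <- utils::combn(r, 2)
    # order by (i, j) so equal-statistic ties resolve to the leftmost pair
    t(p[, order(p[1, ], p[2, ]), drop = FALSE])
  }
}

merge_columns <- function(x, i, j) {
  counts <- x$counts
  groups <- x$groups
  counts[, i] <- counts[, i] + counts[, j]
  groups[[i]] <- c(groups[[i]], groups[[j]])
  counts <- counts[, -j, drop = FALSE]
  groups[j] <- NULL
  colnames(counts) <- vapply(groups, paste, character(1), collapse = "")
  structure(list(counts = counts, groups = groups, ordinal = x$ordinal),
            class = "chi_table")
}

#' Compress a contingency table by chi-square-guided merging
#'
#' Greedy merge-and-backtrack loop. At each step every candidate single
#' merge is scored (all unordered column pairs for a categorical feature,
#' adjacent pairs only for an ordinal one); the merge whose resulting
#' 2 x (r - 1) table has the largest chi-square statistic is selected, and
#' a local 2 x 2 chi-square test on the two columns decides its fate: if
#' p >= alpha the columns are class-indistinguishable and the merge stands,
#' otherwise the merge is backtracked and compression stops. A table may
#' compress all the way to a single column, meaning the feature carries no
#' class signal in this context.
#'
#' @param x A `chi_table`.
#' @param alpha Significance threshold for the local test; default 0.01.
#' @return A list with `table` (the compressed `chi_table`) and
#'   `decisions`, a tibble logging each attempted merge (column pair,
#'   local p-value, accepted flag).
#' @examples
#' t4 <- chi_table(c(30, 100, 120, 31), c(300, 400, 480, 298),
#'                 groups = list("A", "C", "G", "T"))
#' compress_table(t4, alpha = 0.01)$table  # merges to {A,T}, {C,G}
#' @export
compress_table <- function(x, alpha = 0.01) {
  stopifnot(inherits(x, "chi_table"), alpha > 0, alpha < 1)
  res <- compress_core(x$counts[1, ], x$counts[2, ], x$ordinal, alpha)
  groups <- lapply(res$groups, function(idx) {
    unlist(x$groups[idx], use.names = FALSE)
  })
  list(table = chi_table(res$a, res$b, groups = groups, ordinal = x$ordinal),
       decisions = tibble::tibble(col_i = res$log_i, col_j = res$log_j,
                                  local_p = res$log_p,
                                  accepted = res$log_acc))
}

# Merge loop on bare count vectors. Row sums are invariant under column
# merges, so the Pearson statistic decomposes per column as
# (a_j*B - b_j*A)^2 / (A*B*(a_j + b_j)) and every candidate merge rescores
# in O(1): S - t_i - t_j + t_{i+j}. Groups are tracked as index sets into
# the original columns.
compress_core <- function(a, b, ordinal, alpha) {
  a <- as.numeric(a); b <- as.numeric(b)
  groups <- as.list(seq_along(a))
  A <- sum(a); B <- sum(b)
  AB <- A * B
  col_term <- if (AB > 0) {
    function(ai, bi) {
      ci <- ai + bi
      t <- (ai * B - bi * A)^2 / (AB * ci)
      t[ci == 0] <- 0
      t
    }
  } else {
    function(ai, bi) rep(0, length(ai))
  }
  log_i <- integer(0); log_j <- integer(0)
  log_p <- numeric(0); log_acc <- logical(0)
  while (length(a) >= 2) {
    r <- length(a)
    terms <- col_term(a, b)
    if (ordinal) {
      i <- seq_len(r - 1L); j <- i + 1L
    } else {
      cand <- merge_candidates(r, FALSE)
      i <- cand[, 1]; j <- cand[, 2]
    }
    stats <- sum(terms) - terms[i] - terms[j] +
      col_term(a[i] + a[j], b[i] + b[j])
    # ties (within float tolerance) go to the smallest (i, j) pair
    mx <- max(stats)
    best <- which(stats >= mx - 1e-9 * max(1, abs(mx)))[1]
    bi <- i[best]; bj <- j[best]
    p <- local_merge_test(c(a[bi], b[bi]), c(a[bj], b[bj]))
    accepted <- p >= alpha
    log_i <- c(log_i, bi); log_j <- c(log_j, bj)
    log_p <- c(log_p, p); log_acc <- c(log_acc, accepted)
    if (!accepted) break
    a[bi] <- a[bi] + a[bj]; b[bi] <- b[bi] + b[bj]
    groups[[bi]] <- c(groups[[bi]], groups[[bj]])
    a <- a[-bj]; b <- b[-bj]; groups[bj] <- NULL
  }
  list(a = a, b = b, groups = groups, log_i = log_i, log_j = log_j,
       log_p = log_p, log_acc = log_acc)
}

#' Mutual information of a two-row count grid
#'
#' Mutual information in bits between the row variable (class) and the
#' column variable (status), from the empirical joint distribution, with
#' the usual convention 0 log 0 = 0. The normalized value divides by
#' log2(min(rows, cols)) — for a two-row grid, by 1 bit — which is the
#' grid-characteristic normalization used by maximal-information-style
#' measures.
#'
#' @param x A `chi_table` or two-row numeric matrix with positive total.
#' @return A tibble with columns `mi_bits` and `normalized`.
#' @examples
#' grid_mutual_information(rbind(c(0, 4, 6), c(2, 0, 8)))  # normalized 0.31
#' @export
grid_mutual_information <- function(x) {
  m <- as_count_matrix(x)
  n <- sum(m)
  if (n <= 0) stop("degenerate table: all counts are zero", call. = FALSE)
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  pos <- p > 0
  mi <- sum(p[pos] * log2(p[pos] / e[pos]))
  denom <- log2(min(nrow(m), ncol(m)))
  tibble::tibble(mi_bits = mi,
                 normalized = if (denom > 0) mi / denom else 0)
}

#' Read or write a contingency table as TSV
#'
#' Plain three-column representation (group label, positive count,
#' negative count) used by the command-line `inspect` round trip.
#'
#' @param x A `chi_table`.
#' @param path File path.
#' @param ordinal Logical, passed to [chi_table()] when reading.
#' @return `write_chi_table` returns `path` invisibly; `read_chi_table`
#'   returns a `chi_table`.
#' @export
write_chi_table <- function(x, path) {
  stopifnot(inherits(x, "chi_table"))
  df <- data.frame(group = vapply(x$groups, paste, character(1), collapse = ","),
                   positive = x$counts[1, ], negative = x$counts[2, ])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chi_table
#' @export
read_chi_table <- function(path, ordinal = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  chi_table(df$positive, df$negative,
            groups = strsplit(as.character(df$group), ",", fixed = TRUE),
            ordinal = ordinal)
}
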