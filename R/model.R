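#' Binary class entropy
#'
#' Shannon entropy in bits of a two-class sample described by its positive
#' and negative counts; 0 log 0 = 0. Counts may be non-integer.
#'
#' @param pos_count,neg_count Non-negative counts with positive total.
#' @return Entropy in \[0, 1\] bits.
#' @examples
#' entropy(50, 50)    # 1
#' entropy(87, 1687)  # 0.2823
#' @export
entropy <- function(pos_count, neg_count) {
  stopifnot(pos_count >= 0, neg_count >= 0)
  n <- pos_count + neg_count
  if (n <= 0) stop("degenerate set: total count is zero", call. = FALSE)
  p <- c(pos_count, neg_count) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a refinement
#'
#' Weighted entropy of the parent cells minus weighted entropy of their
#' sub-cells, weights |D^j| / |D| taken over the whole sample. Non-negative
#' and bounded by the parent entropy.
#'
#' @param parent Data frame with columns `cell`, `pos`, `neg`.
#' @param children Data frame with columns `cell`, `sub`, `pos`, `neg`;
#'   the sub-cells of each parent cell must account for its counts exactly.
#' @return Gain in bits.
#' @export
information_gain <- function(parent, children) {
  stopifnot(all(c("cell", "pos", "neg") %in% names(parent)),
            all(c("cell", "sub", "pos", "neg") %in% names(children)))
  chk <- dplyr::summarise(dplyr::group_by(children, .data$cell),
                          pos = sum(.data$pos), neg = sum(.data$neg),
                          .groups = "drop")
  m <- dplyr::inner_join(parent, chk, by = "cell",
                         suffix = c("", ".sub"))
  if (nrow(m) != nrow(parent) ||
      any(abs(m$pos - m$pos.sub) > 1e-8) ||
      any(abs(m$neg - m$neg.sub) > 1e-8)) {
    stop("sub-cells do not partition the parent cells", call. = FALSE)
  }
  n <- sum(parent$pos) + sum(parent$neg)
  h <- function(df) {
    tot <- df$pos + df$neg
    keep <- tot > 0
    sum(vapply(which(keep), function(i) {
      (tot[i] / n) * entropy(df$pos[i], df$neg[i])
    }, numeric(1)))
  }
  h(parent) - h(children)
}

#' Gain ratio
#'
#' Information gain divided by the intrinsic value of the split,
#' IV = -sum (|D^j|/|D|) log2(|D^j|/|D|) over the non-empty sub-cells.
#'
#' @param gain Information gain in bits.
#' @param sizes Sub-cell sizes (counts), at least two of them positive.
#' @return The ratio. Errors when only one sub-cell is non-empty (the
#'   split is vacuous and the feature is not a candidate).
#' @export
gain_ratio <- function(gain, sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2) {
    stop("intrinsic value is zero: fewer than two non-empty sub-cells",
         call. = FALSE)
  }
  w <- sizes / sum(sizes)
  gain / (-sum(w * log2(w)))
}

intrinsic_value <- function(sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2) return(0)
  w <- sizes / sum(sizes)
  -sum(w * log2(w))
}

# 2 x r table of a feature over its full domain within one cell of rows
feature_cell_table <- function(values, lab, spec) {
  dom <- spec$domain[[1]]
  code <- match(as.character(values), dom)
  is_pos <- lab == "positive"
  pos <- tabulate(code[is_pos], nbins = length(dom))
  neg <- tabulate(code[!is_pos], nbins = length(dom))
  chi_table(pos, neg, groups = as.list(dom),
            ordinal = spec$kind == "ordinal")
}

#' Iterative gain-ratio feature introduction
#'
#' Builds the rule partition of the decision table. Starting from a single
#' cell holding all training samples, each round considers every
#' not-yet-introduced feature: within every current cell its class-by-
#' status table is compressed ([compress_table()]); the feature is a
#' candidate only if it keeps at least two status groups in at least one
#' cell. Each candidate's information gain over the refined partition and
#' its gain ratio are computed; among candidates whose gain is at least
#' the candidates' mean gain, the one with the largest gain ratio is
#' introduced (ties go to the earliest feature in canonical order:
#' positions 5' to 3', then dinucleotides alphabetically). Cells where the
#' chosen feature compressed to a single group are left unsplit, which is
#' why fitted rules have variable length. The loop stops when no feature
#' is a candidate.
#'
#' @param encoded Data frame from [encode_windows()] with a `label`
#'   column.
#' @param specs Feature specifications ([feature_specs()]).
#' @param alpha Compression threshold.
#' @return List with `features` (ids in introduction order) and `rules`,
#'   a tibble with `rule`, `conditions` (list of named status-group
#'   character vectors), `pos`, `neg`.
#' @export
introduce_features <- function(encoded, specs, alpha = 0.01) {
  stopifnot(all(specs$id %in% names(encoded)), "label" %in% names(encoded))
  lab <- as_label_vector(encoded$label)
  n <- nrow(encoded)
  vals <- lapply(seq_len(nrow(specs)),
                 function(i) as.character(encoded[[specs$id[i]]]))
  names(vals) <- specs$id
  if (length(unique(lab)) < 2) {
    return(list(features = character(0), rules = tibble::tibble(
      rule = 1L, conditions = list(list()),
      pos = sum(lab == "positive"), neg = sum(lab == "negative"))))
  }
  codes <- lapply(specs$id, function(f) {
    match(vals[[f]], specs$domain[[match(f, specs$id)]])
  })
  names(codes) <- specs$id
  domains <- specs$domain
  names(domains) <- specs$id
  is_pos <- lab == "positive"

  cell_of <- rep(1L, n)
  cells <- list(list())  # conditions per cell
  remaining <- specs$id
  introduced <- character(0)

  repeat {
    cell_ids <- seq_along(cells)
    cell_rows <- split(seq_len(n), factor(cell_of, levels = cell_ids))
    cand <- list()
    for (f in remaining) {
      dom <- domains[[f]]
      ordinal <- specs$kind[match(f, specs$id)] == "ordinal"
      code <- codes[[f]]
      groupings <- vector("list", length(cells))
      group_counts <- vector("list", length(cells))
      splits <- FALSE
      for (c_id in cell_ids) {
        rows <- cell_rows[[c_id]]
        if (length(rows) == 0) {
          groupings[[c_id]] <- list(dom)
          group_counts[[c_id]] <- matrix(0, 2, 1)
          next
        }
        rc <- code[rows]
        rp <- is_pos[rows]
        comp <- compress_core(tabulate(rc[rp], nbins = length(dom)),
                              tabulate(rc[!rp], nbins = length(dom)),
                              ordinal, alpha)
        groupings[[c_id]] <- lapply(comp$groups, function(idx) dom[idx])
        group_counts[[c_id]] <- rbind(comp$a, comp$b)
        if (length(comp$groups) >= 2) splits <- TRUE
      }
      if (!splits) next
      # gain over the refined partition, straight from the per-group counts
      sizes <- numeric(0)
      gain_terms <- 0
      for (c_id in cell_ids) {
        cc <- group_counts[[c_id]]
        np <- sum(cc[1, ]); nn <- sum(cc[2, ])
        if (np + nn == 0) next
        parent_h <- ((np + nn) / n) * entropy(np, nn)
        child_h <- 0
        for (j in seq_len(ncol(cc))) {
          tot <- cc[1, j] + cc[2, j]
          sizes <- c(sizes, tot)
          if (tot > 0) child_h <- child_h + (tot / n) * entropy(cc[1, j], cc[2, j])
        }
        gain_terms <- gain_terms + (parent_h - child_h)
      }
      iv <- intrinsic_value(sizes)
      if (iv <= 0) next
      cand[[f]] <- list(gain = gain_terms, ratio = gain_terms / iv,
                        groupings = groupings)
    }
    if (length(cand) == 0) break
    gains <- vapply(cand, `[[`, numeric(1), "gain")
    eligible <- names(cand)[gains >= mean(gains)]
    ratios <- vapply(cand[eligible], `[[`, numeric(1), "ratio")
    # which.max on a vector ordered canonically breaks ties 5'->3', then
    # dinucleotides alphabetically (specs order)
    eligible <- eligible[order(match(eligible, specs$id))]
    ratios <- ratios[eligible]
    mx <- max(ratios)
    chosen <- eligible[which(ratios >= mx - 1e-9 * max(1, abs(mx)))[1]]
    groupings <- cand[[chosen]]$groupings

    new_cells <- list()
    new_cell_of <- integer(n)
    for (c_id in cell_ids) {
      rows <- cell_rows[[c_id]]
      g <- groupings[[c_id]]
      if (length(g) < 2) {           # feature uninformative here: unsplit
        new_cells[[length(new_cells) + 1L]] <- cells[[c_id]]
        new_cell_of[rows] <- length(new_cells)
        next
      }
      for (grp in g) {
        cond <- cells[[c_id]]
        cond[[chosen]] <- grp
        new_cells[[length(new_cells) + 1L]] <- cond
        if (length(rows)) {
          in_g <- vals[[chosen]][rows] %in% grp
          new_cell_of[rows[in_g]] <- length(new_cells)
        }
      }
    }
    cells <- new_cells
    cell_of <- new_cell_of
    introduced <- c(introduced, chosen)
    remaining <- setdiff(remaining, chosen)
    if (length(remaining) == 0) break
  }

  counts <- t(vapply(seq_along(cells), function(c_id) {
    rows <- which(cell_of == c_id)
    c(sum(lab[rows] == "positive"), sum(lab[rows] == "negative"))
  }, numeric(2)))
  list(features = introduced,
       rules = tibble::tibble(rule = seq_along(cells), conditions = cells,
                              pos = counts[, 1], neg = counts[, 2]))
}

#' Build a (re)balanced decision table from a rule partition
#'
#' Attaches per-rule weighted negative counts. In balanced mode every
#' rule's raw negative count is multiplied by theta = N+ / N-, so the
#' negative row carries the same total mass as the positive row and the
#' plus-one chi-square decision is no longer dominated by the majority
#' class. Weighted counts are stored unrounded; one-decimal rounding is
#' display only.
#'
#' @param partition Result of [introduce_features()], or its `rules`
#'   tibble.
#' @param balanced Logical; reweight negatives by N+/N- (default `TRUE`).
#' @param theta Optional explicit weight overriding the default.
#' @return A `chidt_dtable`: the rules tibble with `neg_weighted` added
#'   and attributes `theta`, `balanced`.
#' @examples
#' part <- tibble::tibble(rule = 1:4, conditions = replicate(4, list()),
#'                        pos = c(38, 12, 26, 11),
#'                        neg = c(184, 1026, 289, 188))
#' build_decision_table(part)  # weighted negatives 9.5, 52.9, 14.9, 9.7
#' @export
build_decision_table <- function(partition, balanced = TRUE, theta = NULL) {
  rules <- if (is.data.frame(partition)) partition else partition$rules
  stopifnot(all(c("rule", "conditions", "pos", "neg") %in% names(rules)))
  n_pos <- sum(rules$pos)
  n_neg <- sum(rules$neg)
  if (is.null(theta)) {
    if (balanced) {
      if (n_neg <= 0) stop("cannot balance: no negative samples", call. = FALSE)
      theta <- n_pos / n_neg
    } else {
      theta <- 1
    }
  }
  out <- dplyr::mutate(tibble::as_tibble(rules),
                       neg_weighted = .data$neg * theta)
  attr(out, "theta") <- theta
  attr(out, "balanced") <- balanced
  class(out) <- c("chidt_dtable", class(out))
  out
}

match_rule <- function(encoded, rules) {
  n <- nrow(encoded)
  matched <- integer(n)
  for (k in seq_len(nrow(rules))) {
    cond <- rules$conditions[[k]]
    hit <- rep(TRUE, n)
    for (f in names(cond)) {
      hit <- hit & (as.character(encoded[[f]]) %in% cond[[f]])
    }
    dup <- hit & matched != 0L
    if (any(dup)) stop("sample matches more than one rule", call. = FALSE)
    matched[hit] <- k
  }
  if (any(matched == 0L)) stop("sample matches no rule", call. = FALSE)
  matched
}

#' Classify encoded samples with the plus-one chi-square rule
#'
#' For each sample the matched rule k is perturbed under both class
#' hypotheses: chi2_pos is the Pearson statistic of the whole 2 x K
#' weighted table with the rule's positive count incremented by one, and
#' chi2_neg the statistic with its weighted negative count incremented by
#' one. The sample is called positive exactly when chi2_pos > chi2_neg
#' (ties negative); the difference is kept as a continuous ranking score.
#'
#' @param encoded Data frame of encoded samples ([encode_windows()]).
#' @param dtable A `chidt_dtable` from [build_decision_table()].
#' @return Tibble `rule`, `chi2_pos`, `chi2_neg`, `score`, `label`.
#' @export
classify_samples <- function(encoded, dtable) {
  stopifnot(inherits(dtable, "chidt_dtable"))
  a <- dtable$pos
  b <- dtable$neg_weighted
  k_match <- match_rule(encoded, dtable)
  uk <- unique(k_match)
  chi_tab <- matrix(NA_real_, nrow = max(uk), ncol = 2)
  for (k in uk) {
    ap <- a; ap[k] <- ap[k] + 1
    bn <- b; bn[k] <- bn[k] + 1
    chi_tab[k, 1] <- chi2_stat(rbind(ap, b))
    chi_tab[k, 2] <- chi2_stat(rbind(a, bn))
  }
  cp <- chi_tab[k_match, 1]
  cn <- chi_tab[k_match, 2]
  tibble::tibble(rule = k_match, chi2_pos = cp, chi2_neg = cn,
                 score = cp - cn,
                 label = ifelse(cp > cn, "positive", "negative"))
}

#' Fit a chi-square decision-table donor-site classifier
#'
#' Composes the full training pipeline: encode the labeled windows,
#' introduce features by compressed-table gain ratio
#' ([introduce_features()]), and build the (balanced) decision table
#' ([build_decision_table()]). Fitting is deterministic: no parameters are
#' optimised and no randomness is involved.
#'
#' @param data Data frame with columns `window` (equal-length GT-excluded
#'   windows) and `label` (`"positive"`/`"negative"`).
#' @param alpha Local chi-square threshold for table compression;
#'   default 0.01.
#' @param balanced Use the theta-reweighted balanced table (default) or
#'   the raw imbalanced one.
#' @param upstream Number of window positions 5' of the GT; default 3.
#' @param theta Optional explicit negative-count weight.
#' @param compositional Include the 16 dinucleotide-count features
#'   (default `TRUE`); positional-only models are less robust to
#'   frameshift errors in the tested sequence.
#' @return A `chidt_model` object; see [predict.chidt_model()],
#'   [tidy.chidt_model()], [glance.chidt_model()].
#' @examples
#' sim <- simulate_donor_data(n_pos = 60, n_neg = 120, seed = 1)
#' win <- dplyr::mutate(sim, window = extract_window(seq))
#' fit <- chidt_fit(win)
#' predict(fit, win[1:5, ])
#' @export
chidt_fit <- function(data, alpha = 0.01, balanced = TRUE, upstream = 3,
                      theta = NULL, compositional = TRUE) {
  stopifnot(all(c("window", "label") %in% names(data)))
  len <- unique(nchar(data$window))
  stopifnot(length(len) == 1)
  specs <- feature_specs(upstream, len - upstream)
  enc <- encode_windows(data, specs = specs)
  if (!compositional) specs <- specs[specs$kind == "categorical", ]
  lab <- as_label_vector(enc$label)
  if (length(unique(lab)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  part <- introduce_features(enc, specs, alpha = alpha)
  dtable <- build_decision_table(part, balanced = balanced, theta = theta)
  structure(list(specs = specs, features = part$features, dtable = dtable,
                 alpha = alpha, balanced = balanced,
                 upstream = upstream, downstream = len - upstream,
                 n_pos = sum(lab == "positive"),
                 n_neg = sum(lab == "negative")),
            class = "chidt_model")
}

#' @export
print.chidt_model <- function(x, ...) {
  cat(sprintf(
    "<chidt_model: %d rules from %d introduced features (%s table)>\n",
    nrow(x$dtable), length(x$features),
    if (x$balanced) "balanced" else "imbalanced"))
  cat(sprintf("  window: -%d..+%d (GT excluded), alpha = %g\n",
              x$upstream, x$downstream, x$alpha))
  cat(sprintf("  training: %d positive / %d negative, theta = %.6g\n",
              x$n_pos, x$n_neg, attr(x$dtable, "theta")))
  invisible(x)
}

#' Predict donor-site labels for new windows
#'
#' @param object A fitted `chidt_model`.
#' @param newdata Data frame with a `window` column (same length as the
#'   training windows); other columns are carried through.
#' @param ... Unused.
#' @return The input tibble with `rule`, `chi2_pos`, `chi2_neg`, `score`
#'   and predicted `label` columns appended (`.pred_label` when the input
#'   already has a `label` column).
#' @export
predict.chidt_model <- function(object, newdata, ...) {
  stopifnot("window" %in% names(newdata))
  enc <- encode_windows(newdata, specs = object$specs)
  res <- classify_samples(enc, object$dtable)
  out <- tibble::as_tibble(newdata)
  if ("label" %in% names(out)) names(res)[names(res) == "label"] <- ".pred_label"
  dplyr::bind_cols(out, res)
}

rule_text <- function(cond) {
  if (length(cond) == 0) return("(TRUE)")
  paste(vapply(names(cond), function(f) {
    sprintf("(%s=%s)", f, paste(cond[[f]], collapse = ""))
  }, character(1)), collapse = "&")
}

#' Tidy and summarise fitted decision-table models
#'
#' `tidy()` returns one row per decision rule with its conditions rendered
#' as text, positive count, raw and weighted negative counts. `glance()`
#' returns a one-row model summary. `tidy()` on a `chi_table` returns its
#' group/count rows.
#'
#' @param x A `chidt_model` (or `chi_table` for the table method).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.chidt_model <- function(x, ...) {
  d <- x$dtable
  tibble::tibble(
    rule = d$rule,
    conditions = vapply(d$conditions, rule_text, character(1)),
    pos = d$pos, neg = d$neg, neg_weighted = d$neg_weighted)
}

#' @rdname tidy.chidt_model
#' @export
glance.chidt_model <- function(x, ...) {
  tibble::tibble(
    n_rules = nrow(x$dtable), n_features = length(x$features),
    n_pos = x$n_pos, n_neg = x$n_neg,
    theta = attr(x$dtable, "theta"), balanced = x$balanced,
    alpha = x$alpha, upstream = x$upstream, downstream = x$downstream)
}

#' Generics for model tidiers
#'
#' Broom-style generics re-exported locally so `tidy()` and `glance()`
#' work without attaching another package.
#'
#' @param x Object to tidy or summarise.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Save or load a fitted model as JSON
#'
#' The file records the window configuration, alpha, the introduced
#' feature order, and each rule's conditions and integer counts; theta and
#' the weighted negative counts are reconstructed on load from the stored
#' integers, so a save/load round trip is bit-exact.
#'
#' @param model A `chidt_model`.
#' @param path File path.
#' @return `write_chidt_model` returns `path` invisibly;
#'   `read_chidt_model` returns the model.
#' @export
write_chidt_model <- function(model, path) {
  stopifnot(inherits(model, "chidt_model"))
  d <- model$dtable
  obj <- list(
    format = "chidt_model", version = 1L,
    upstream = model$upstream, downstream = model$downstream,
    alpha = model$alpha, balanced = model$balanced,
    features = as.list(model$features),
    rules = lapply(seq_len(nrow(d)), function(k) {
      list(conditions = d$conditions[[k]], pos = d$pos[k], neg = d$neg[k])
    }))
  default_theta <- if (model$balanced) model$n_pos / model$n_neg else 1
  if (!isTRUE(all.equal(attr(d, "theta"), default_theta))) {
    obj$theta_override <- attr(d, "theta")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_chidt_model
#' @export
read_chidt_model <- function(path) {
  obj <- jsonlite::read_json(path)
  stopifnot(identical(obj$format, "chidt_model"))
  rules <- tibble::tibble(
    rule = seq_along(obj$rules),
    conditions = lapply(obj$rules, function(r) {
      lapply(r$conditions, function(g) unlist(g, use.names = FALSE))
    }),
    pos = vapply(obj$rules, function(r) as.numeric(r$pos), numeric(1)),
    neg = vapply(obj$rules, function(r) as.numeric(r$neg), numeric(1)))
  theta_override <- if (is.numeric(obj$theta_override)) {
    obj$theta_override
  } else {
    NULL
  }
  dtable <- build_decision_table(rules, balanced = isTRUE(obj$balanced),
                                 theta = theta_override)
  specs <- feature_specs(obj$upstream, obj$downstream)
  structure(list(specs = specs,
                 features = unlist(obj$features) %||% character(0),
                 dtable = dtable, alpha = obj$alpha,
                 balanced = isTRUE(obj$balanced),
                 upstream = obj$upstream, downstream = obj$downstream,
                 n_pos = sum(rules$pos), n_neg = sum(rules$neg)),
            class = "chidt_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
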