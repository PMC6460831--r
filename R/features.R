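BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(outer(BASES, BASES, paste0))  # AA, CA, GA, TA, AC, ...

position_labels <- function(upstream, downstream) {
  c(paste0("P", -rev(seq_len(upstream))), paste0("P+", seq_len(downstream)))
}

#' Feature specifications for a GT-anchored window
#'
#' The default 11-bp window (3 nt upstream, 8 nt downstream of the
#' conserved GT, GT itself excluded) yields 27 features: 11 positional
#' features — the base at each labeled offset, categorical over A/C/G/T —
#' and 16 compositional features — the count of each overlapping
#' dinucleotide in the window, ordinal over 0..(window length - 1).
#'
#' @param upstream,downstream Number of window positions 5' and 3' of the
#'   GT anchor; defaults 3 and 8.
#' @return A tibble with columns `id`, `kind` (`"categorical"` or
#'   `"ordinal"`) and `domain` (list column of ordered status values).
#' @examples
#' feature_specs()  # 27 rows
#' @export
feature_specs <- function(upstream = 3, downstream = 8) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream >= 2)
  len <- upstream + downstream
  dn <- sort(DINUCS)
  tibble::tibble(
    id = c(position_labels(upstream, downstream), dn),
    kind = c(rep("categorical", len), rep("ordinal", 16)),
    domain = c(rep(list(BASES), len),
               rep(list(as.character(0:(len - 1))), 16))
  )
}

#' Extract prediction windows around GT anchors
#'
#' Concatenates the `upstream` bases immediately 5' of the GT with the
#' `downstream` bases immediately 3' of it; the GT dinucleotide itself is
#' excluded. Coordinates are 1-based: `gt_pos` indexes the G of the GT
#' (71 in the standard 140-nt window convention).
#'
#' @param sequence Character vector of DNA sequences (A/C/G/T).
#' @param gt_pos Integer vector (recycled) of 1-based G positions.
#' @param upstream,downstream Window flank sizes; defaults 3 and 8.
#' @return Character vector of windows of length `upstream + downstream`.
#' @examples
#' extract_window("AAACCCGTAAGTTTTT", 7)  # "CCCAAGTTTTT"
#' @export
extract_window <- function(sequence, gt_pos = 71, upstream = 3, downstream = 8) {
  sequence <- toupper(sequence)
  n <- max(length(sequence), length(gt_pos))
  sequence <- rep_len(sequence, n)
  gt_pos <- rep_len(as.integer(gt_pos), n)
  if (any(gt_pos - upstream < 1) ||
      any(gt_pos + 1 + downstream > nchar(sequence))) {
    stop("window out of sequence bounds", call. = FALSE)
  }
  anchor <- substr(sequence, gt_pos, gt_pos + 1)
  if (any(anchor != "GT")) {
    stop("anchor is not GT at position ", gt_pos[which(anchor != "GT")[1]],
         call. = FALSE)
  }
  w <- paste0(substr(sequence, gt_pos - upstream, gt_pos - 1),
              substr(sequence, gt_pos + 2, gt_pos + 1 + downstream))
  bad <- grepl("[^ACGT]", w)
  if (any(bad)) {
    stop("non-ACGT base inside window for record ", which(bad)[1],
         call. = FALSE)
  }
  w
}

#' Encode windows as positional and compositional feature vectors
#'
#' @param data A data frame with a `window` column of equal-length ACGT
#'   strings; any other columns (e.g. `label`) are carried through.
#' @param specs Feature specifications from [feature_specs()]; inferred
#'   from the window length (with default 3 upstream) when `NULL`.
#' @param upstream Upstream flank used to label positions when `specs` is
#'   inferred.
#' @return The input tibble with one column per feature appended:
#'   positional columns hold single bases, dinucleotide columns hold
#'   integer counts. Dinucleotide counts always sum to window length - 1.
#' @examples
#' encode_windows(tibble::tibble(window = "ACACACACACA"))
#' @export
encode_windows <- function(data, specs = NULL, upstream = 3) {
  stopifnot(is.data.frame(data), "window" %in% names(data))
  w <- toupper(data$window)
  if (length(w) == 0) stop("no windows to encode", call. = FALSE)
  len <- unique(nchar(w))
  if (length(len) != 1) stop("windows must have equal length", call. = FALSE)
  if (any(grepl("[^ACGT]", w))) stop("non-ACGT base in window", call. = FALSE)
  if (is.null(specs)) specs <- feature_specs(upstream, len - upstream)
  pos_ids <- specs$id[specs$kind == "categorical"]
  stopifnot(length(pos_ids) == len)
  out <- tibble::as_tibble(data)
  for (i in seq_len(len)) {
    out[[pos_ids[i]]] <- substr(w, i, i)
  }
  di <- vapply(seq_len(len - 1), function(i) substr(w, i, i + 1),
               character(length(w)))
  di <- matrix(di, nrow = length(w))
  for (d in specs$id[specs$kind == "ordinal"]) {
    out[[d]] <- as.integer(rowSums(di == d))
  }
  out
}

#' Per-position class-discrimination profile
#'
#' For every position of a set of labeled, aligned full-length sequences,
#' builds the 2 x 4 base-by-class contingency table, compresses it
#' ([compress_table()]), and records the chi-square test of the compressed
#' table as log10(1/p). Large values flag positions whose base composition
#' differs between true and false donor sites; the profile is the basis
#' for choosing the prediction window.
#'
#' @param data Data frame with columns `seq` (equal-length sequences,
#'   aligned on the GT anchor) and `label` (`"positive"`/`"negative"`).
#' @param gt_pos 1-based position of the G of the anchor GT; default 71.
#' @param alpha Compression threshold passed to [compress_table()].
#' @return A tibble of class `chidt_importance`: `offset` (signed label
#'   relative to GT, anchor positions excluded), `position` (1-based
#'   column), `r` (compressed width), `statistic`, `log10_inv_p`.
#' @export
position_importance <- function(data, gt_pos = 71, alpha = 0.01) {
  stopifnot(all(c("seq", "label") %in% names(data)))
  s <- toupper(data$seq)
  len <- unique(nchar(s))
  stopifnot(length(len) == 1)
  lab <- as_label_vector(data$label)
  if (length(unique(lab)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  positions <- setdiff(seq_len(len), c(gt_pos, gt_pos + 1))
  rows <- lapply(positions, function(i) {
    base <- substr(s, i, i)
    tab <- base_class_table(base, lab)
    comp <- compress_table(tab, alpha = alpha)$table
    r <- ncol(comp$counts)
    if (r < 2) {
      stat <- 0
      lp <- 0
    } else {
      stat <- chi2_stat(comp)
      lp <- -chi2_pvalue(stat, df = r - 1, log10p = TRUE)
    }
    tibble::tibble(
      offset = if (i < gt_pos) i - gt_pos else i - gt_pos - 1,
      position = i, r = r, statistic = stat, log10_inv_p = lp)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chidt_importance", class(out))
  out
}

base_class_table <- function(base, lab) {
  pos <- vapply(BASES, function(b) sum(base == b & lab == "positive"),
                numeric(1))
  neg <- vapply(BASES, function(b) sum(base == b & lab == "negative"),
                numeric(1))
  chi_table(pos, neg, groups = as.list(BASES), ordinal = FALSE)
}

#' Choose a prediction window from an importance profile
#'
#' The default rule returns the fixed 11-bp window (3 upstream, 8
#' downstream). The data-driven rule takes a reference offset (default -2),
#' and returns the maximal contiguous run of positions flanking the GT
#' whose log10(1/p) is at least the reference position's value; if that run
#' is empty on both sides it falls back to the default with a warning.
#'
#' @param profile A `chidt_importance` tibble from [position_importance()].
#' @param method `"fixed"` (default) or `"data_driven"`.
#' @param reference Reference offset for the data-driven rule.
#' @param default Fallback window as `c(upstream, downstream)`.
#' @return Named integer vector `c(upstream = , downstream = )`.
#' @export
select_window <- function(profile, method = c("fixed", "data_driven"),
                          reference = -2, default = c(3L, 8L)) {
  method <- match.arg(method)
  out <- c(upstream = default[1], downstream = default[2])
  if (method == "fixed") return(out)
  stopifnot(nrow(profile) > 0, reference %in% profile$offset)
  thr <- profile$log10_inv_p[profile$offset == reference][1]
  keep <- profile$offset[profile$log10_inv_p >= thr & profile$log10_inv_p > 0]
  up <- 0L
  while ((-(up + 1L)) %in% keep) up <- up + 1L
  down <- 0L
  while ((down + 1L) %in% keep) down <- down + 1L
  if (up + down < 2) {
    warning("degenerate importance profile; falling back to default window")
    return(out)
  }
  c(upstream = up, downstream = down)
}

#' Enumerate candidate donor sites in a genomic sequence
#'
#' Every GT dinucleotide with full flanks inside the sequence is a
#' candidate site (the GT-AG rule: true donors almost always start with
#' GT, but decoy GTs vastly outnumber them). Windows containing non-ACGT
#' characters are skipped and counted.
#'
#' @param sequence A single DNA string.
#' @param upstream,downstream Flank sizes; defaults 3 and 8.
#' @param id Sequence identifier copied into the output.
#' @return A tibble `seq_id`, `gt_pos` (1-based G position), `window`,
#'   with attribute `skipped` giving the number of candidates dropped for
#'   ambiguous bases.
#' @examples
#' enumerate_candidate_sites("AAAGTAAAAAAAA")
#' @export
enumerate_candidate_sites <- function(sequence, upstream = 3, downstream = 8,
                                      id = "seq") {
  stopifnot(length(sequence) == 1)
  s <- toupper(sequence)
  hits <- gregexpr("GT", s, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  hits <- hits[hits - upstream >= 1 & hits + 1 + downstream <= nchar(s)]
  if (length(hits) == 0) {
    out <- tibble::tibble(seq_id = character(), gt_pos = integer(),
                          window = character())
    attr(out, "skipped") <- 0L
    return(out)
  }
  w <- paste0(substr(rep(s, length(hits)), hits - upstream, hits - 1),
              substr(rep(s, length(hits)), hits + 2, hits + 1 + downstream))
  ok <- !grepl("[^ACGT]", w)
  out <- tibble::tibble(seq_id = id, gt_pos = as.integer(hits[ok]),
                        window = w[ok])
  attr(out, "skipped") <- sum(!ok)
  out
}

as_label_vector <- function(label) {
  if (is.logical(label)) {
    return(ifelse(label, "positive", "negative"))
  }
  lab <- as.character(label)
  ok <- lab %in% c("positive", "negative")
  if (!all(ok)) stop("labels must be 'positive' or 'negative'", call. = FALSE)
  lab
}
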