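#' Read DNA sequences from FASTA or line-per-sequence text
#'
#' Sniffs the dialect: files whose first non-blank character is `>` are
#' parsed as FASTA (via Biostrings), anything else as one sequence per
#' line. Sequences are uppercased; CRLF line endings are tolerated.
#'
#' @param path File path.
#' @param label Optional label (`"positive"`/`"negative"`) attached to
#'   every record, following the convention of distributing true and
#'   false sites as separate files.
#' @return Tibble `id`, `seq` (and `label` when given).
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0) stop("empty sequence file: ", path, call. = FALSE)
  if (startsWith(trimws(first[1]), ">")) {
    set <- Biostrings::readBStringSet(path)
    out <- tibble::tibble(id = trimws(names(set)),
                          seq = unname(toupper(gsub("\\s", "",
                                                    as.character(set)))))
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    out <- tibble::tibble(id = sprintf("seq_%05d", seq_along(lines)),
                          seq = toupper(lines))
  }
  if (!is.null(label)) out$label <- as_label_vector(rep(label, nrow(out)))
  out
}

#' Write sequences as FASTA
#'
#' @param data Data frame with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line-wrap width; default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(data)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(data))) {
    s <- data$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(paste0(">", data$id[i]),
                 substring(s, starts, pmin(starts + width - 1, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read labeled windows from paired FASTA files or a label TSV
#'
#' @param pos_path,neg_path FASTA (or line-per-sequence) files of positive
#'   and negative records.
#' @param labels_path Alternative to `neg_path`: a single sequence file
#'   (`pos_path`) plus a two-column TSV `id`, `label`.
#' @return Tibble `id`, `seq`, `label`.
#' @export
read_labeled <- function(pos_path, neg_path = NULL, labels_path = NULL) {
  if (!is.null(neg_path)) {
    return(dplyr::bind_rows(read_fasta(pos_path, "positive"),
                            read_fasta(neg_path, "negative")))
  }
  stopifnot(!is.null(labels_path))
  seqs <- read_fasta(pos_path)
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(lab)))
  out <- dplyr::inner_join(seqs, tibble::as_tibble(lab), by = "id")
  if (nrow(out) != nrow(seqs)) {
    stop("labels missing for some records", call. = FALSE)
  }
  out$label <- as_label_vector(out$label)
  out
}

seq_checksum <- function(seqs) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(seqs, tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble a training or test set at a given class ratio
#'
#' Samples the requested numbers of positive and negative records without
#' replacement from two pools, deterministically under the seed. When
#' `exclude` is given (e.g. a previously assembled test set), those record
#' ids are removed from the pools first, enforcing train/test
#' disjointness.
#'
#' @param pos_pool,neg_pool Tibbles with `id`, `seq` columns.
#' @param n_pos,n_neg Requested counts.
#' @param seed Integer seed.
#' @param exclude Optional tibble whose `id`s are withheld from the pools.
#' @return Tibble `id`, `seq`, `label`, with attribute `manifest`: a
#'   one-row tibble of counts, ratio label and a sequence checksum.
#' @export
assemble_dataset <- function(pos_pool, neg_pool, n_pos, n_neg, seed = 1,
                             exclude = NULL) {
  if (!is.null(exclude)) {
    pos_pool <- pos_pool[!pos_pool$id %in% exclude$id, ]
    neg_pool <- neg_pool[!neg_pool$id %in% exclude$id, ]
  }
  if (nrow(pos_pool) < n_pos || nrow(neg_pool) < n_neg) {
    stop("pool too small for requested counts", call. = FALSE)
  }
  withr::local_seed(seed)
  pos <- pos_pool[sample(nrow(pos_pool), n_pos), ]
  neg <- neg_pool[sample(nrow(neg_pool), n_neg), ]
  pos$label <- "positive"
  neg$label <- "negative"
  out <- dplyr::bind_rows(pos, neg)
  attr(out, "manifest") <- tibble::tibble(
    n_pos = n_pos, n_neg = n_neg,
    ratio = paste0("1:", round(n_neg / max(n_pos, 1))),
    seed = seed, checksum = seq_checksum(out$seq))
  out
}

#' Scan genomic sequences for donor-site candidates
#'
#' Enumerates every GT with full flanks in each input sequence
#' ([enumerate_candidate_sites()]), classifies the windows with a fitted
#' model, and returns a BED-like table. Windows containing ambiguous
#' bases are skipped and tallied in the `skipped` attribute. The reverse
#' strand is not scanned unless requested.
#'
#' @param data Tibble `id`, `seq` of genomic sequences.
#' @param model A fitted `chidt_model`.
#' @param reverse Also scan the reverse complement; default `FALSE`.
#' @return Tibble `seq_id`, `gt_pos`, `strand`, `window`, `chi2_pos`,
#'   `chi2_neg`, `score`, `label`.
#' @export
scan_sequences <- function(data, model, reverse = FALSE) {
  stopifnot(inherits(model, "chidt_model"),
            all(c("id", "seq") %in% names(data)))
  one_strand <- function(seqs, ids, strand) {
    cands <- purrr::map2(seqs, ids, function(s, i) {
      enumerate_candidate_sites(s, model$upstream, model$downstream, id = i)
    })
    skipped <- sum(vapply(cands, function(x) attr(x, "skipped"), integer(1)))
    cands <- dplyr::bind_rows(cands)
    if (nrow(cands) == 0) {
      out <- tibble::tibble(seq_id = character(), gt_pos = integer(),
                            strand = character(), window = character())
      attr(out, "skipped") <- skipped
      return(out)
    }
    cands$strand <- strand
    attr(cands, "skipped") <- skipped
    cands
  }
  fwd <- one_strand(data$seq, data$id, "+")
  hits <- fwd
  skipped <- attr(fwd, "skipped")
  if (reverse) {
    rc <- reverse_complement(data$seq)
    rev <- one_strand(rc, data$id, "-")
    skipped <- skipped + attr(rev, "skipped")
    hits <- dplyr::bind_rows(fwd, rev)
  }
  if (nrow(hits) == 0) {
    attr(hits, "skipped") <- skipped
    return(hits)
  }
  out <- predict(model, hits)
  attr(out, "skipped") <- skipped
  out
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Run the simulate-train-evaluate pipeline
#'
#' Convenience wrapper for an offline end-to-end run: simulate a training
#' set at the configured imbalance, an independent balanced test set, fit
#' the model, predict the test windows, and score them.
#'
#' @param n_pos,n_neg Training-set composition.
#' @param n_test Positives (= negatives) in the balanced test set.
#' @param pwm Positional model; default [donor_pwm()].
#' @param alpha,balanced Passed to [chidt_fit()].
#' @param seed Integer seed driving both simulations (test data uses an
#'   offset substream so train and test are independent).
#' @return List `model`, `predictions`, `metrics`.
#' @export
run_pipeline <- function(n_pos = 200, n_neg = 2000, n_test = 300,
                         pwm = donor_pwm(), alpha = 0.01, balanced = TRUE,
                         seed = 1) {
  train <- simulate_donor_data(n_pos, n_neg, pwm = pwm, seed = seed)
  test <- simulate_donor_data(n_test, n_test, pwm = pwm, seed = seed + 10000L)
  train$window <- extract_window(train$seq)
  test$window <- extract_window(test$seq)
  model <- chidt_fit(train, alpha = alpha, balanced = balanced)
  preds <- predict(model, test)
  list(model = model, predictions = preds,
       metrics = evaluate_predictions(preds))
}
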