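#' Position-weight model of the donor splice-site consensus
#'
#' Per-offset base probabilities for the window flanking the invariant GT.
#' The default encodes the canonical mammalian donor consensus MAG|GTRAGT:
#' strong A at -2, G at -1, A/G at +1, A at +2, G at +3, T at +4, a weak G
#' preference at +5. Offsets further downstream carry a mild G/T-enriched,
#' intron-like composition rather than plain background: a true donor
#' window straddles an exon|intron boundary, and this composition shift is
#' the signal the dinucleotide-count features pick up.
#' `sharpness` scales the positional signal log-linearly around the
#' background: each column is proportional to
#' `background * (consensus / background)^sharpness`, renormalized. 0
#' collapses every position to background, 1 is the canonical consensus,
#' and values above 1 exaggerate the consensus into an artificially clean
#' motif — the family used to study how performance degrades as the
#' positional signal weakens.
#'
#' @param sharpness Signal strength, non-negative; default 1.
#' @param upstream,downstream Window flanks; defaults 3 and 8. Offsets
#'   beyond the built-in consensus (past +5 or before -3) use background.
#' @param background Base probabilities of the background composition.
#' @return A 4 x (upstream + downstream) probability matrix, rows A/C/G/T,
#'   columns labeled by signed offset; attribute `background` keeps the
#'   background vector.
#' @export
donor_pwm <- function(sharpness = 1, upstream = 3, downstream = 8,
                      background = c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)) {
  stopifnot(sharpness >= 0, abs(sum(background) - 1) < 1e-8)
  consensus <- list(
    `-3` = c(A = 0.33, C = 0.37, G = 0.18, T = 0.12),
    `-2` = c(A = 0.60, C = 0.13, G = 0.14, T = 0.13),
    `-1` = c(A = 0.09, C = 0.04, G = 0.79, T = 0.08),
    `+1` = c(A = 0.53, C = 0.03, G = 0.40, T = 0.04),
    `+2` = c(A = 0.71, C = 0.08, G = 0.12, T = 0.09),
    `+3` = c(A = 0.07, C = 0.06, G = 0.84, T = 0.03),
    `+4` = c(A = 0.16, C = 0.15, G = 0.19, T = 0.50),
    `+5` = c(A = 0.22, C = 0.18, G = 0.40, T = 0.20))
  intron_bg <- c(A = 0.22, C = 0.14, G = 0.30, T = 0.34)
  offs <- c(paste0("", -rev(seq_len(upstream))), paste0("+", seq_len(downstream)))
  m <- vapply(offs, function(o) {
    cons <- consensus[[o]] %||%
      (if (startsWith(o, "+")) intron_bg else background)
    col <- background * (cons / background)^sharpness
    col / sum(col)
  }, numeric(4))
  rownames(m) <- BASES
  attr(m, "background") <- background
  m
}

sample_bases <- function(n, probs) {
  BASES[sample.int(4, n, replace = TRUE, prob = probs)]
}

random_seq <- function(n, len, background) {
  m <- matrix(sample_bases(n * len, background), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Simulate labeled donor-site sequences
#'
#' Emulates the structure of the standard benchmark records: fixed-length
#' sequences with the invariant GT at a fixed anchor. Positives draw their
#' window offsets from the positional model and everything else from the
#' background; negatives are pure background with GT forced at the anchor
#' — GT decoys whose discrimination must come entirely from the flanking
#' positional structure, since both classes share the same background
#' composition.
#'
#' @param n_pos,n_neg Numbers of positive and negative records.
#' @param pwm Positional model from [donor_pwm()].
#' @param seq_length Record length; default 140.
#' @param gt_pos 1-based anchor position of the G; default 71.
#' @param seed Integer seed; the same seed reproduces the data exactly.
#' @return Tibble `id`, `seq`, `label`.
#' @examples
#' simulate_donor_data(5, 5, seed = 1)
#' @export
simulate_donor_data <- function(n_pos, n_neg, pwm = donor_pwm(),
                                seq_length = 140, gt_pos = 71, seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  upstream <- sum(!startsWith(colnames(pwm), "+"))
  downstream <- ncol(pwm) - upstream
  stopifnot(gt_pos - upstream >= 1, gt_pos + 1 + downstream <= seq_length)
  background <- attr(pwm, "background")
  withr::local_seed(seed)
  mk_pos <- function(n) {
    if (n == 0) return(character(0))
    win <- apply(pwm, 2, function(p) sample_bases(n, p))
    win <- matrix(win, nrow = n)
    left <- random_seq(n, gt_pos - upstream - 1, background)
    right_len <- seq_length - gt_pos - 1 - downstream
    right <- random_seq(n, right_len, background)
    paste0(left,
           apply(win[, seq_len(upstream), drop = FALSE], 1, paste, collapse = ""),
           "GT",
           apply(win[, upstream + seq_len(downstream), drop = FALSE], 1,
                 paste, collapse = ""),
           right)
  }
  mk_neg <- function(n) {
    if (n == 0) return(character(0))
    s <- random_seq(n, seq_length, background)
    paste0(substr(s, 1, gt_pos - 1), "GT", substr(s, gt_pos + 2, seq_length))
  }
  tibble::tibble(
    id = c(sprintf("pos_%05d", seq_len(n_pos)),
           sprintf("neg_%05d", seq_len(n_neg))),
    seq = c(mk_pos(n_pos), mk_neg(n_neg)),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)))
}

#' Imbalance presets for training-set composition
#'
#' The positive:negative ratios studied for decision-table robustness,
#' from balanced (1:1) up to the extreme 1:135 of the full benchmark
#' (2000 positives against 271,132 negatives).
#'
#' @return Tibble `ratio`, `n_pos`, `n_neg`.
#' @export
imbalance_presets <- function() {
  tibble::tibble(
    ratio = c("1:1", "1:10", "1:20", "1:50", "1:135"),
    n_pos = rep(2000L, 5),
    n_neg = c(2000L, 20000L, 40000L, 100000L, 271132L))
}

#' Introduce random frameshift errors into sequences
#'
#' Emulates insertion/deletion sequencing errors: each position is hit
#' independently with probability `rate`; a hit is, with equal
#' probability, a deletion of that base or an insertion of one uniformly
#' random base after it. Expected length is unchanged.
#'
#' @param sequences Character vector of DNA sequences.
#' @param rate Per-base error probability in \[0, 1); default 0.01.
#' @param seed Integer seed.
#' @return Character vector of mutated sequences.
#' @export
mutate_indels <- function(sequences, rate = 0.01, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(sequences)
  withr::local_seed(seed)
  vapply(sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(ch)) < rate
    if (!any(hit)) return(s)
    is_del <- stats::runif(length(ch)) < 0.5
    out <- ch
    ins <- sample(BASES, length(ch), replace = TRUE)
    out[hit & is_del] <- ""
    w <- hit & !is_del
    out[w] <- paste0(ch[w], ins[w])
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Worked decision-table and grid fixtures
#'
#' The small printed examples used throughout the documentation and test
#' suite: the 87/1687 two-feature decision table in imbalanced and
#' theta-reweighted form, the 2000/271,132 reweighting factor with two of
#' its rule counts, and the 2 x 3 mutual-information grid.
#'
#' @return Named list: `table_imbalanced` (2 x 4 matrix, rows
#'   positive/negative), `theta_small` (87/1687), `theta_main`
#'   (2000/271132), `raw_negatives_main` (c(47512, 368)), `mi_grid`
#'   (2 x 3 matrix).
#' @export
worked_fixtures <- function() {
  tab <- rbind(positive = c(38, 12, 26, 11),
               negative = c(184, 1026, 289, 188))
  colnames(tab) <- c("ACT.AT", "ACT.GC", "G.AT", "G.GC")
  list(table_imbalanced = tab,
       theta_small = 87 / 1687,
       theta_main = 2000 / 271132,
       raw_negatives_main = c(47512, 368),
       mi_grid = rbind(c(0, 4, 6), c(2, 0, 8)))
}
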