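# Bayesian decision inference engine: posterior probability that a
# diagnosis element is present given a positive assessment finding,
# estimated from a patient co-occurrence registry.

#' Estimate the probability triple from registry counts
#'
#' A registry row cross-tabulates, over patients, a positive/negative
#' assessment finding against presence/absence of a diagnosis element
#' (defining characteristic, related factor or risk factor). The three
#' probabilities feeding the posterior are estimated by relative frequency,
#' optionally with a symmetric pseudo-count:
#' \itemize{
#'   \item `p_pos_given_dc = (n_pos_dc + s) / (n_pos_dc + n_neg_dc + 2s)`
#'   \item `p_dc = (n_pos_dc + n_neg_dc + s) / (total + 2s)`
#'   \item `p_pos_given_nondc = (n_pos_nondc + s) / (n_pos_nondc + n_neg_nondc + 2s)`
#' }
#'
#' @param n_pos_dc patients with a positive finding and the element present.
#' @param n_neg_dc negative finding, element present.
#' @param n_pos_nondc positive finding, element absent.
#' @param n_neg_nondc negative finding, element absent.
#' @param smoothing non-negative pseudo-count `s` (default 0: plain relative
#'   frequencies, with an error on an empty margin).
#' @return data frame with columns `p_pos_given_dc`, `p_dc`,
#'   `p_pos_given_nondc` (one row per input row).
#' @export
#' @examples
#' estimate_probabilities(9, 1, 2, 8)  # 0.9, 0.5, 0.2
estimate_probabilities <- function(n_pos_dc, n_neg_dc, n_pos_nondc,
                                   n_neg_nondc, smoothing = 0) {
  s <- smoothing
  assert_that(is.numeric(s) && length(s) == 1L && s >= 0,
              "smoothing must be a single non-negative number")
  counts <- cbind(n_pos_dc, n_neg_dc, n_pos_nondc, n_neg_nondc)
  assert_that(all(counts >= 0) && all(counts == floor(counts)),
              "registry counts must be non-negative integers")
  total <- rowSums(counts)
  assert_that(all(total >= 1), "registry row has no patients (total = 0)")
  dc_margin <- counts[, 1] + counts[, 2]
  nondc_margin <- counts[, 3] + counts[, 4]
  if (s == 0 && any(dc_margin == 0 | nondc_margin == 0)) {
    stop("empty DC or non-DC margin with smoothing = 0: conditional probability undefined",
         call. = FALSE)
  }
  data.frame(
    p_pos_given_dc = (counts[, 1] + s) / (dc_margin + 2 * s),
    p_dc = (dc_margin + s) / (total + 2 * s),
    p_pos_given_nondc = (counts[, 3] + s) / (nondc_margin + 2 * s))
}

#' Posterior probability of an element given a positive finding
#'
#' Bayes' rule for one association:
#' `P(DC|+) = P(+|DC) P(DC) / (P(+|DC) P(DC) + P(+|Non_DC) (1 - P(DC)))`.
#' An uninformative finding (`P(+|DC) = P(+|Non_DC)`) returns the prior
#' `P(DC)`; a perfectly specific finding (`P(+|Non_DC) = 0`) returns 1.
#'
#' @param p_pos_given_dc probability of a positive finding given the element
#'   is present.
#' @param p_dc marginal probability of the element across patients.
#' @param p_pos_given_nondc probability of a positive finding given the
#'   element is absent.
#' @return posterior probability vector in \[0, 1\].
#' @export
#' @examples
#' bayes_posterior(0.9, 0.2, 0.1)  # 0.18 / 0.26 = 0.6923
bayes_posterior <- function(p_pos_given_dc, p_dc, p_pos_given_nondc) {
  if (is.data.frame(p_pos_given_dc)) {
    p <- p_pos_given_dc
    p_pos_given_dc <- p$p_pos_given_dc
    p_dc <- p$p_dc
    p_pos_given_nondc <- p$p_pos_given_nondc
  }
  check_prob(p_pos_given_dc, "p_pos_given_dc")
  check_prob(p_dc, "p_dc")
  check_prob(p_pos_given_nondc, "p_pos_given_nondc")
  num <- p_pos_given_dc * p_dc
  den <- num + p_pos_given_nondc * (1 - p_dc)
  if (any(den <= 0)) {
    stop("zero denominator: a positive finding is impossible under both hypotheses",
         call. = FALSE)
  }
  num / den
}

#' Build a Bayesian indicator table from a co-occurrence registry
#'
#' One indicator per registry association: the score is the posterior
#' probability of the element given a positive finding, the level comes from
#' the same thresholds as the CDV engine by default (major >= 0.80, minor
#' in \[0.50, 0.80)). The same registry schema covers all three association
#' families (assessment item to defining characteristic, defining
#' characteristic to related factor, assessment item to risk factor),
#' distinguished by the element type in the knowledge base.
#'
#' @param registry data frame with columns `item_id`, `dx_code`,
#'   `element_id`, `n_pos_dc`, `n_neg_dc`, `n_pos_nondc`, `n_neg_nondc`.
#' @param kb a `knowledge_base`; registry associations must resolve.
#' @param smoothing pseudo-count passed to [estimate_probabilities()].
#' @param major,minor classification thresholds.
#' @return an [indicator_table] with `engine = "bayes"`.
#' @export
build_bayes_indicators <- function(registry, kb, smoothing = 0,
                                   major = 0.80, minor = 0.50) {
  stopifnot(inherits(kb, "knowledge_base"))
  registry <- as.data.frame(registry)
  need <- c("item_id", "dx_code", "element_id", "n_pos_dc", "n_neg_dc",
            "n_pos_nondc", "n_neg_nondc")
  assert_that(all(need %in% names(registry)),
              sprintf("registry missing column(s): %s",
                      paste(setdiff(need, names(registry)), collapse = ", ")))
  if (nrow(registry) == 0L) {
    return(indicator_table(registry[0, c("item_id", "dx_code", "element_id")],
                           engine = "bayes",
                           params = list(smoothing = smoothing,
                                         major = major, minor = minor)))
  }
  check_resolves(registry, kb, "registry")
  p <- estimate_probabilities(registry$n_pos_dc, registry$n_neg_dc,
                              registry$n_pos_nondc, registry$n_neg_nondc,
                              smoothing = smoothing)
  entries <- registry[c("item_id", "dx_code", "element_id")]
  entries$score <- bayes_posterior(p)
  entries$level <- classify_level(entries$score, major, minor)
  indicator_table(entries, engine = "bayes",
                  params = list(smoothing = smoothing,
                                major = major, minor = minor))
}

#' Read a patient co-occurrence registry from CSV
#'
#' Columns `item_id,dx_code,element_id,n_pos_dc,n_neg_dc,n_pos_nondc,n_neg_nondc`.
#'
#' @param path CSV file path.
#' @return data frame of registry counts.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("registry file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "dx_code", "element_id", "n_pos_dc", "n_neg_dc",
            "n_pos_nondc", "n_neg_nondc")
  assert_that(all(need %in% names(df)),
              sprintf("registry CSV missing column(s): %s",
                      paste(setdiff(need, names(df)), collapse = ", ")))
  df
}
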