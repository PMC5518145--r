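# Design weights for the growth approach. Notation follows standard complex
# survey usage: strata k, PSUs i, households j, individuals q.
#   G_k   estimated population of stratum k (str_pop)
#   g_ik  estimated population of PSU i in stratum k (psu_pop)
#   n_k   PSUs selected in stratum k; n_k_star found-and-sampled
#   M_ik  households enumerated in PSU i; m_ik sampled; m_ik_star responding
#   b_ik  proportion of PSU households inside a manually drawn segment
#   u_ijk eligible individuals in household j; u_ijk_star responding
# Weights reflect inclusion probabilities of the final (grown) PSUs, not of
# individual grid cells.

chk_ledger <- function(G_k, g_ik, n_k, M_ik = NULL, m_ik = NULL,
                       n_k_star = NULL, m_ik_star = NULL) {
  if (any(g_ik <= 0) || any(G_k < g_ik)) stop("need G_k >= g_ik > 0")
  if (any(n_k <= 0)) stop("n_k must be positive")
  if (!is.null(M_ik) && (any(m_ik <= 0) || any(m_ik > M_ik)))
    stop("need 0 < m_ik <= M_ik")
  if (!is.null(n_k_star) && (any(n_k_star <= 0) || any(n_k_star > n_k)))
    stop("need 0 < n_k_star <= n_k")
  if (!is.null(m_ik_star) && (any(m_ik_star <= 0) || any(m_ik_star > m_ik)))
    stop("need 0 < m_ik_star <= m_ik")
  invisible(TRUE)
}

#' Household selection (base) weight
#'
#' Inverse probability that PSU i was selected by PPES and household j was
#' selected within it:
#' \deqn{w_{ij.b} = \frac{G_k / g_{ik}}{n_k} \times \frac{M_{ik}}{m_{ik}}}
#'
#' @param G_k estimated stratum population.
#' @param g_ik estimated PSU population.
#' @param n_k PSUs selected in the stratum.
#' @param M_ik households enumerated in the PSU during fieldwork.
#' @param m_ik households sampled in the PSU.
#' @return the base weight (vectorized over PSUs).
#' @export
household_base_weight <- function(G_k, g_ik, n_k, M_ik, m_ik) {
  chk_ledger(G_k, g_ik, n_k, M_ik, m_ik)
  (G_k / g_ik) / n_k * (M_ik / m_ik)
}

#' Base weight for a manually segmented PSU
#'
#' As [household_base_weight()] with the extra factor 1 / `b_ik`, where
#' `b_ik` is the proportion of the PSU's households inside the manually
#' drawn segment (approximated by counting buildings in satellite imagery).
#'
#' @inheritParams household_base_weight
#' @param b_ik segment household proportion, in (0, 1].
#' @export
segmented_base_weight <- function(G_k, g_ik, n_k, M_ik, m_ik, b_ik) {
  if (any(b_ik <= 0) || any(b_ik > 1)) stop("b_ik must lie in (0, 1]")
  household_base_weight(G_k, g_ik, n_k, M_ik, m_ik) / b_ik
}

#' Household response weight
#'
#' Inverse probability that the PSU was found and sampled and the household
#' was found and responded:
#' \deqn{w_{ij.r} = \frac{n_k}{n_k^*} \times \frac{m_{ik}}{m_{ik}^*}}
#'
#' @inheritParams household_base_weight
#' @param n_k_star PSUs found and sampled in the stratum.
#' @param m_ik_star households found and responding in the PSU.
#' @export
household_response_weight <- function(n_k, n_k_star, m_ik, m_ik_star) {
  if (any(n_k_star <= 0) || any(n_k_star > n_k)) stop("need 0 < n_k_star <= n_k")
  if (any(m_ik_star <= 0) || any(m_ik_star > m_ik)) stop("need 0 < m_ik_star <= m_ik")
  (n_k / n_k_star) * (m_ik / m_ik_star)
}

#' Individual response weight
#'
#' Extends [household_response_weight()] by the within-household individual
#' response factor `u_ijk / u_ijk_star`.
#'
#' @inheritParams household_response_weight
#' @param u_ijk eligible individuals in the household.
#' @param u_ijk_star responding individuals in the household.
#' @export
individual_response_weight <- function(n_k, n_k_star, m_ik, m_ik_star,
                                       u_ijk, u_ijk_star) {
  if (any(u_ijk_star <= 0) || any(u_ijk_star > u_ijk))
    stop("need 0 < u_ijk_star <= u_ijk")
  household_response_weight(n_k, n_k_star, m_ik, m_ik_star) *
    (u_ijk / u_ijk_star)
}

#' Combined household and individual sample weights from a ledger
#'
#' The ledger is a flat table with one row per household, keyed by
#' (`stratum_id`, `psu_id`, `household_id`) and carrying the fieldwork
#' tallies: `G_k`, `g_ik`, `n_k`, `n_k_star`, `M_ik`, `m_ik`, `m_ik_star`,
#' optional `b_ik` (default 1), and — for individual weights — `u_ijk`,
#' `u_ijk_star`. Output weights are
#' `w_ij = w_ij.b x w_ij.r` per household and
#' `w_ijq = w_ij.b x w_ijq.r` per individual-bearing row.
#'
#' @param ledger data.frame as described (e.g. read from CSV with
#'   [utils::read.csv()]).
#' @return list with `households` (ledger keys plus `w_b`, `w_r`, `w_ij`)
#'   and `individuals` (`w_ijq`, rows with individual tallies; `NULL` when
#'   none are present).
#' @export
combined_weights <- function(ledger) {
  req <- c("stratum_id", "psu_id", "household_id", "G_k", "g_ik", "n_k",
           "n_k_star", "M_ik", "m_ik", "m_ik_star")
  miss <- setdiff(req, names(ledger))
  if (length(miss)) stop("ledger lacks column(s): ", paste(miss, collapse = ", "))
  b <- if ("b_ik" %in% names(ledger)) ifelse(is.na(ledger$b_ik), 1, ledger$b_ik) else 1
  w_b <- segmented_base_weight(ledger$G_k, ledger$g_ik, ledger$n_k,
                               ledger$M_ik, ledger$m_ik, b)
  w_r <- household_response_weight(ledger$n_k, ledger$n_k_star,
                                   ledger$m_ik, ledger$m_ik_star)
  hh <- data.frame(ledger[c("stratum_id", "psu_id", "household_id")],
                   w_b = w_b, w_r = w_r, w_ij = w_b * w_r)
  ind <- NULL
  if (all(c("u_ijk", "u_ijk_star") %in% names(ledger))) {
    has <- !is.na(ledger$u_ijk) & !is.na(ledger$u_ijk_star)
    if (any(has)) {
      w_qr <- individual_response_weight(
        ledger$n_k[has], ledger$n_k_star[has], ledger$m_ik[has],
        ledger$m_ik_star[has], ledger$u_ijk[has], ledger$u_ijk_star[has])
      ind <- data.frame(ledger[has, c("stratum_id", "psu_id", "household_id")],
                        w_b = w_b[has], w_qr = w_qr, w_ijq = w_b[has] * w_qr)
    }
  }
  list(households = hh, individuals = ind)
}
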