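#' The Escherichia coli SOS-response case study
#'
#' Executable fixture for the nine-gene SOS DNA-damage-repair network
#' (genes `lexA`, `recA`, `recF`, `rpoS`, `rpoD`, `umuDC`, `dinI`, `ssB`,
#' `rpoH`; 43 signed regulatory edges) together with the published kinetic
#' parameter estimates (`P`, `S` per gene; `Q`, `R` per edge, keyed to the
#' edge order) and the experimentally observed steady-state concentrations
#' used for validation.  `umuDC` is the canonical name for the gene that
#' some summaries print as `umuD`.
#'
#' Edge ordering note: edges are numbered 1..43 grouped by target gene in
#' the order lexA, recA, recF, rpoS, rpoD, umuDC, dinI, ssB, rpoH,
#' activators first.  For three targets (rpoD, umuDC, dinI) the pairing of
#' inhibitor edges with threshold/cooperativity indices follows the unique
#' assignment under which the published parameter set reproduces the
#' published steady states exactly (to the rounding of the printed
#' values); see the package vignette for the consistency analysis.
#' [sos_edge_table()] lists the full mapping for review.
#'
#' @return `load_sos()`: object of class `sos_case_study` with elements
#'   `network` ([grn_network()]), `params` ([grn_params()]),
#'   `experimental_ss` (named vector, mM), and `published_ss` /
#'   `published_ss_pso` (the two published model steady-state columns,
#'   used only for transcription cross-checks).
#' @examples
#' sos <- load_sos()
#' parameter_count(sos$network)   # 104, 61, 43
#' @export
load_sos <- function() {
  genes <- c("lexA", "recA", "recF", "rpoS", "rpoD", "umuDC", "dinI",
             "ssB", "rpoH")
  reg <- c(
    "recA", "recF", "rpoD", "dinI", "ssB", "umuDC",           # -> lexA
    "recF", "rpoD", "dinI", "lexA", "ssB", "umuDC",           # -> recA
    "rpoD", "rpoS", "ssB", "umuDC",                           # -> recF
    "rpoD",                                                   # -> rpoS
    "recF", "recA", "dinI", "rpoH", "umuDC", "ssB", "lexA",   # -> rpoD
    "rpoD", "recF", "recA", "dinI", "ssB", "lexA",            # -> umuDC
    "rpoD", "recF", "recA", "umuDC", "ssB", "lexA",           # -> dinI
    "dinI", "rpoD", "recF", "recA", "umuDC", "lexA",          # -> ssB
    "rpoD")                                                   # -> rpoH
  tgt <- rep(genes, c(6L, 6L, 4L, 1L, 7L, 6L, 6L, 6L, 1L))
  sgn <- c("+", "+", "+", "+", "-", "-",
           "+", "+", "+", "-", "-", "-",
           "+", "+", "-", "-",
           "+",
           "+", "+", "+", "+", "-", "-", "-",
           "+", "+", "+", "-", "-", "-",
           "+", "+", "+", "-", "-", "-",
           "+", "+", "+", "+", "-", "-",
           "+")
  network <- grn_network(genes, regulator = reg, target = tgt, sign = sgn)

  P <- c(0.82645, 3.0312, 26.844, 0.22028, 22.807, 30.438, 5.7443,
         9.6769, 1809.6)
  S <- c(0.56596, 0.06717, 1.151, 0.03181, 0.97227, 0.037697, 0.024872,
         0.60515, 258.52)
  Q <- c(1.6273, 0.58209, 0.65218, 14.988, 17.705, 272.67,
         11.981, 56.946, 4.9391, 34.691, 4.779, 18.819,
         61.511, 1.3297, 8.4207, 11.72,
         14.013,
         11.867, 9.5381, 1.7108, 4.6155, 23.779, 39.778, 3.0976,
         1.5401, 0.9762, 13.822, 1.3686e6, 0.50903, 150.6,
         9.3893, 134.06, 15.778, 2.4818, 8.9587, 40.718,
         14.545, 376.12, 351.21, 27.191, 133.91, 9.7889,
         14.225)
  R <- c(1.6354, 1.6833, 1.8982, 2.3757, 2.2303, 1.5392,
         2.674, 3.5452, 1.4626, 1.3153, 1.8499, 3.0102,
         4.9999, 1.1567, 1.8104, 2.117,
         2.049,
         1.8588, 2.2855, 3.3169, 2.3944, 2.9639, 1.7128, 2.0704,
         0.60901, 1.3191, 4.0316, 1.8207, 1.9367, 1.3081,
         1.9267, 1.9118, 2.3397, 1.9367, 1.7976, 1.3055,
         2.6053, 1.1819, 1.8328, 1.9916, 2.9068, 2.0699,
         2.041)
  params <- grn_params(P = P, S = S, Q = Q, R = R, network = network)

  experimental_ss <- c(lexA = 11.471, recA = 11.795, recF = 8.975,
                       rpoS = 10.383, rpoD = 9.4618, umuDC = 7.8192,
                       dinI = 9.9169, ssB = 10.213, rpoH = 8.5983)
  published_ss <- c(lexA = 11.192, recA = 13.326, recF = 9.8327,
                    rpoS = 9.6427, rpoD = 11.322, umuDC = 9.6932,
                    dinI = 11.542, ssB = 11.334, rpoH = 9.6991)
  published_ss_pso <- c(lexA = 11.4599, recA = 16.492, recF = 4.87727,
                        rpoS = 3.46706, rpoD = 5.20705, umuDC = 9.35587,
                        dinI = 12.1365, ssB = 11.2432, rpoH = 1.12474)

  # fixture invariants: fail loudly if any transcription drifts
  stopifnot(network$n_genes == 9L, network$n_edges == 43L,
            identical(unname(parameter_count(network)), c(104L, 61L, 43L)),
            P[9] == 1809.6, S[9] == 258.52, Q[28] == 1.3686e6,
            R[13] == 4.9999)

  structure(list(network = network, params = params,
                 experimental_ss = experimental_ss,
                 published_ss = published_ss,
                 published_ss_pso = published_ss_pso),
            class = "sos_case_study")
}

#' @export
print.sos_case_study <- function(x, ...) {
  cat("<sos_case_study> E. coli SOS response: 9 genes, 43 edges,",
      "104 parameters\n")
  invisible(x)
}

#' Edge-by-edge parameter cross-reference for the SOS fixture
#'
#' One row per edge `k = 1..43`: target, regulator, sign, and the
#' threshold `Q[k]` / cooperativity `R[k]` keyed to it, so the
#' transcription of the published estimates is reviewable at a glance.
#'
#' @return A data frame with columns `edge`, `target`, `regulator`,
#'   `sign`, `Q`, `R`.
#' @export
sos_edge_table <- function() {
  sos <- load_sos()
  net <- sos$network
  data.frame(edge = seq_len(net$n_edges),
             target = net$genes[net$tgt],
             regulator = net$genes[net$reg],
             sign = ifelse(net$sign > 0, "+", "-"),
             Q = sos$params$Q, R = sos$params$R,
             stringsAsFactors = FALSE)
}

#' Recompute the SOS steady-state validation table
#'
#' Solves the steady-state system of the SOS model with the published
#' parameter estimates, starting from the experimental steady-state
#' column, and reports per-gene experimental versus model values together
#' with the sum of squared errors.
#'
#' @param x_guess starting state for [steady_state()] (default: the
#'   experimental column, which makes the computation self-contained).
#' @return Data frame with columns `gene`, `experimental`, `model`, and
#'   attribute `sse` (sum over genes of squared experimental-model
#'   differences, mM^2).
#' @export
reproduce_table2 <- function(x_guess = NULL) {
  sos <- load_sos()
  if (is.null(x_guess)) x_guess <- sos$experimental_ss
  ss <- steady_state(sos$network, sos$params, x_guess)
  out <- data.frame(gene = sos$network$genes,
                    experimental = unname(sos$experimental_ss),
                    model = unname(ss),
                    stringsAsFactors = FALSE)
  attr(out, "sse") <- steady_state_sse(ss, sos$experimental_ss)
  out
}
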