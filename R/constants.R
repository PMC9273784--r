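# Sequence and propensity constants for alpha-synuclein (UniProt P37840).

.ASYN_WT <- paste0(
  "MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYV",
  "GSKTKEGVVHGVATVAEKTKEQVTNVGGAVVTGVTAVAQK",
  "TVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP",
  "DNEAYEMPSEEGYQDYEPEA"
)

# Chou & Fasman (1978) beta-sheet conformational parameters P(beta),
# as distributed by the ExPASy ProtScale "beta-sheet / Chou & Fasman" scale.
.CF_BETA <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
  Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
  L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
  S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
)

#' alpha-Synuclein sequences
#'
#' The 140-residue wild-type human alpha-synuclein sequence and the familial
#' Parkinson's disease point variants A30P, E46K and A53T.
#'
#' @param variant One of `"WT"`, `"A30P"`, `"E46K"`, `"A53T"`.
#' @return A single character string of 140 one-letter amino-acid codes.
#' @examples
#' substr(asyn_sequence("A53T"), 53, 53)  # "T"
#' @export
asyn_sequence <- function(variant = c("WT", "A30P", "E46K", "A53T")) {
  variant <- match.arg(variant)
  s <- .ASYN_WT
  sub1 <- function(s, pos, aa) {
    substr(s, pos, pos) <- aa
    s
  }
  switch(variant,
    WT = s,
    A30P = sub1(s, 30L, "P"),
    E46K = sub1(s, 46L, "K"),
    A53T = sub1(s, 53L, "T")
  )
}

#' Domain boundaries of alpha-synuclein
#'
#' Standard domain bounds: N-terminal 1-60, NAC 61-95, C-terminal 96-140.
#' The window 1-95 (N-terminal + NAC) is the region over which helix/sheet
#' residue counts are accumulated for the two-state (B vs HB) statistics.
#'
#' @return Named list of integer ranges (`c(start, end)`).
#' @export
asyn_domains <- function() {
  list(
    n_terminal = c(1L, 60L),
    nac = c(61L, 95L),
    c_terminal = c(96L, 140L),
    ss_count_region = c(1L, 95L)
  )
}
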