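# Core reaction kernels for the cell-free TX-TL models.
#
# State ordering is fixed as (d_T, d_G, m_T, m_G, p_T, p_G, R) and is written
# into every trace header: DNA, mRNA and protein for the polymerase (T) and
# the reporter (G), plus one lumped resource R (NTPs + charged tRNAs).
# All concentrations are non-dimensional.

.STATE_NAMES <- c("d_T", "d_G", "m_T", "m_G", "p_T", "p_G", "R")

#' Model state vector
#'
#' Builds the seven-species state of the resource-dependent TX-TL model:
#' DNA (`d_T`, `d_G`), mRNA (`m_T`, `m_G`) and protein (`p_T`, `p_G`) for the
#' T7 RNA polymerase and the eGFP reporter, plus a single lumped resource `R`
#' representing NTPs and aminoacyl-tRNAs. Concentrations are non-dimensional.
#'
#' @param d_T,d_G DNA template concentrations (polymerase, reporter).
#' @param m_T,m_G mRNA concentrations.
#' @param p_T,p_G protein concentrations.
#' @param R lumped resource concentration.
#' @return Named numeric vector of length 7 in the canonical state order.
#' @examples
#' txtl_state(d_G = 1, p_T = 1, R = 1)
#' @export
txtl_state <- function(d_T = 0, d_G = 0, m_T = 0, m_G = 0,
                       p_T = 0, p_G = 0, R = 0) {
  s <- c(d_T = d_T, d_G = d_G, m_T = m_T, m_G = m_G,
         p_T = p_T, p_G = p_G, R = R)
  check_state(s)
  s
}

check_state <- function(state) {
  if (length(state) != 7L) {
    stop("state must have exactly 7 components (d_T, d_G, m_T, m_G, p_T, p_G, R)",
         call. = FALSE)
  }
  if (any(!is.finite(state))) stop("state components must be finite", call. = FALSE)
  if (any(state < 0)) stop("state components must be >= 0", call. = FALSE)
  invisible(state)
}

#' Model parameters
#'
#' Parameter container shared by both reaction kernels. The resource-dependent
#' model uses `alpha` (transcription rate constant, per time per DNA per
#' polymerase), `beta` (translation rate constant, per time per mRNA) and `K`
#' (half-saturation constant of the resource Hill factor). The
#' resource-independent alternative additionally uses `E_total` (shared
#' translational enzyme pool) and `K_M` (competitive Michaelis constant in
#' total-mRNA units). First-order degradation of mRNA and protein is available
#' through `delta_m`/`delta_p` but is off by default: in the minimal model,
#' dilution is the only removal process.
#'
#' Defaults are the calibrated non-dimensional values used throughout the
#' package; see the methods vignette for the calibration procedure.
#'
#' @param alpha transcription rate constant (> 0), per minute.
#' @param beta translation rate constant (> 0), per minute.
#' @param K resource half-saturation constant (> 0).
#' @param E_total total shared translational enzyme (> 0), alternative model.
#' @param K_M Michaelis constant for competitive translation (> 0),
#'   alternative model.
#' @param delta_m,delta_p first-order mRNA / protein degradation rates
#'   (>= 0), per minute; default 0.
#' @return Object of class `txtl_params`.
#' @examples
#' txtl_params()
#' txtl_params(alpha = 0.2, K = 0.05)
#' @export
txtl_params <- function(alpha = 0.1, beta = 0.1, K = 0.1,
                        E_total = 1, K_M = 1,
                        delta_m = 0, delta_p = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("K must be a single finite value > 0", call. = FALSE)
  if (E_total <= 0 || K_M <= 0)
    stop("E_total and K_M must be > 0", call. = FALSE)
  if (delta_m < 0 || delta_p < 0)
    stop("degradation rates must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, K = K,
                 E_total = E_total, K_M = K_M,
                 delta_m = delta_m, delta_p = delta_p),
            class = "txtl_params")
}

#' @export
print.txtl_params <- function(x, ...) {
  cat("TX-TL model parameters (non-dimensional, rates per minute)\n")
  cat(sprintf("  resource-dependent : alpha = %g, beta = %g, K = %g\n",
              x$alpha, x$beta, x$K))
  cat(sprintf("  shared-enzyme alt. : E_total = %g, K_M = %g\n",
              x$E_total, x$K_M))
  cat(sprintf("  degradation        : delta_m = %g, delta_p = %g\n",
              x$delta_m, x$delta_p))
  invisible(x)
}

#' Resource availability Hill factor
#'
#' The fraction `R / (R + K)` by which both transcription and translation
#' rates are modulated when the lumped resource is scarce. It is 0.5 at
#' half-saturation (`R = K`) and approaches 1 as `R` grows.
#'
#' @param R resource concentration(s), >= 0.
#' @param K half-saturation constant, > 0.
#' @return Dimensionless value(s) in `[0, 1]`.
#' @examples
#' hill_factor(1, 1)   # 0.5
#' hill_factor(3, 1)   # 0.75
#' @export
hill_factor <- function(R, K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be > 0", call. = FALSE)
  if (any(!is.finite(R)) || any(R < 0)) stop("R must be >= 0", call. = FALSE)
  R / (R + K)
}

#' Resource-dependent model right-hand side
#'
#' Derivatives of the seven-species TX-TL model between dilution events.
#' Transcription of each gene is linear in its DNA template and in the T7
#' polymerase protein; translation is linear in mRNA; both are modulated by
#' the resource Hill factor `R/(R + K)`; the resource is consumed at the
#' summed transcription plus translation rate. DNA is inert (changed only by
#' dilution, which is handled by the chemostat engine).
#'
#' @param state named state vector as from [txtl_state()].
#' @param params a [txtl_params()] object.
#' @return Named derivative vector of length 7.
#' @seealso [resource_independent_rhs()], [run_chemostat()]
#' @examples
#' s <- txtl_state(d_T = 0.2, d_G = 1, p_T = 1, R = 1)
#' resource_dependent_rhs(s, txtl_params())
#' @export
resource_dependent_rhs <- function(state, params) {
  check_state(state)
  stopifnot(inherits(params, "txtl_params"))
  s <- as.numeric(state)
  names(s) <- .STATE_NAMES
  h <- s[["R"]] / (s[["R"]] + params$K)
  tx_T <- params$alpha * s[["d_T"]] * s[["p_T"]] * h
  tx_G <- params$alpha * s[["d_G"]] * s[["p_T"]] * h
  tl_T <- params$beta * s[["m_T"]] * h
  tl_G <- params$beta * s[["m_G"]] * h
  c(d_T = 0, d_G = 0,
    m_T = tx_T - params$delta_m * s[["m_T"]],
    m_G = tx_G - params$delta_m * s[["m_G"]],
    p_T = tl_T - params$delta_p * s[["p_T"]],
    p_G = tl_G - params$delta_p * s[["p_G"]],
    R   = -(tx_T + tx_G + tl_T + tl_G))
}

#' Resource-independent (shared-enzyme) model right-hand side
#'
#' Alternative kernel in which only translational loading couples the two
#' genes: a fixed pool of translational enzyme `E_total` is shared between
#' the mRNAs under competitive Michaelis-Menten kinetics, so total
#' translational flux saturates in total mRNA and each gene's share equals
#' its mRNA fraction. Transcription is unmodulated and the resource species
#' is held fixed (zero derivative). The competitive-saturation form is this
#' package's reconstruction of a shared-enzyme mechanism; see the vignette.
#'
#' @inheritParams resource_dependent_rhs
#' @return Named derivative vector of length 7 (`R` component is 0).
#' @examples
#' s <- txtl_state(d_G = 1, m_T = 2, m_G = 2, p_T = 1, R = 1)
#' resource_independent_rhs(s, txtl_params(E_total = 1, K_M = 1, beta = 1))
#' @export
resource_independent_rhs <- function(state, params) {
  check_state(state)
  stopifnot(inherits(params, "txtl_params"))
  s <- as.numeric(state)
  names(s) <- .STATE_NAMES
  denom <- params$K_M + s[["m_T"]] + s[["m_G"]]
  tx_T <- params$alpha * s[["d_T"]] * s[["p_T"]]
  tx_G <- params$alpha * s[["d_G"]] * s[["p_T"]]
  tl_T <- params$beta * params$E_total * s[["m_T"]] / denom
  tl_G <- params$beta * params$E_total * s[["m_G"]] / denom
  c(d_T = 0, d_G = 0,
    m_T = tx_T - params$delta_m * s[["m_T"]],
    m_G = tx_G - params$delta_m * s[["m_G"]],
    p_T = tl_T - params$delta_p * s[["p_T"]],
    p_G = tl_G - params$delta_p * s[["p_G"]],
    R   = 0)
}

#' Gene set for the generalized multi-gene model
#'
#' Describes N co-expressed genes by their DNA/mRNA/protein indices in an
#' extended state vector, generalizing the two-gene model to multi-component
#' regeneration (e.g. several aminoacyl-tRNA synthetases alongside the
#' polymerase and reporter). By default genes occupy a block layout
#' (all DNAs, then all mRNAs, then all proteins) followed by the resource.
#'
#' @param genes character vector of gene identifiers.
#' @param requires_t7 logical, recycled; whether each gene's transcription is
#'   proportional to the polymerase protein (TRUE for T7 promoters).
#' @param polymerase identifier of the gene whose protein acts as the
#'   polymerase; ignored if no gene requires it.
#' @param d_idx,m_idx,p_idx optional explicit state indices per gene.
#' @param r_idx optional resource index (default: one past the last protein).
#' @return Object of class `gene_set` (a data frame with attributes).
#' @examples
#' gene_set(c("T7", "eGFP"))
#' @export
gene_set <- function(genes, requires_t7 = TRUE, polymerase = genes[1],
                     d_idx = NULL, m_idx = NULL, p_idx = NULL, r_idx = NULL) {
  n <- length(genes)
  if (n > 0L && anyDuplicated(genes)) stop("gene identifiers must be unique", call. = FALSE)
  requires_t7 <- rep_len(as.logical(requires_t7), n)
  if (is.null(d_idx)) d_idx <- seq_len(n)
  if (is.null(m_idx)) m_idx <- n + seq_len(n)
  if (is.null(p_idx)) p_idx <- 2L * n + seq_len(n)
  idx <- c(d_idx, m_idx, p_idx)
  if (n > 0L && anyDuplicated(idx)) stop("state indices must be unique", call. = FALSE)
  if (is.null(r_idx)) r_idx <- if (n > 0L) max(idx) + 1L else 1L
  if (r_idx %in% idx) stop("resource index collides with a gene index", call. = FALSE)
  gs <- data.frame(gene = as.character(genes), d_idx = d_idx, m_idx = m_idx,
                   p_idx = p_idx, requires_t7 = requires_t7,
                   stringsAsFactors = FALSE)
  attr(gs, "r_idx") <- as.integer(r_idx)
  attr(gs, "polymerase") <- if (n > 0L && any(requires_t7)) as.character(polymerase) else NA_character_
  if (!is.na(attr(gs, "polymerase")) && !attr(gs, "polymerase") %in% gs$gene)
    stop("polymerase must name one of the genes", call. = FALSE)
  class(gs) <- c("gene_set", "data.frame")
  gs
}

#' Generalized multi-gene resource-dependent right-hand side
#'
#' Applies the resource-dependent rate laws gene-by-gene on an arbitrary state
#' layout described by a [gene_set()]. For the canonical two-gene set
#' (polymerase + reporter, block layout) it reduces exactly to
#' [resource_dependent_rhs()].
#'
#' @param state numeric state vector; length must cover all indices in
#'   `genes` plus the resource index.
#' @param params a [txtl_params()] object.
#' @param genes a [gene_set()].
#' @return Numeric derivative vector, same length as `state`. Species not
#'   referenced by `genes` get derivative 0.
#' @examples
#' gs <- gene_set(c("T7", "eGFP"))
#' s <- txtl_state(d_T = 0.2, d_G = 1, p_T = 1, R = 1)
#' generalized_rhs(as.numeric(s), txtl_params(), gs)
#' @export
generalized_rhs <- function(state, params, genes) {
  stopifnot(inherits(params, "txtl_params"), inherits(genes, "gene_set"))
  n <- nrow(genes)
  r_idx <- attr(genes, "r_idx")
  need <- if (n > 0L) max(genes$d_idx, genes$m_idx, genes$p_idx, r_idx) else r_idx
  if (length(state) < need)
    stop("state vector shorter than the indices declared in the gene set", call. = FALSE)
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and >= 0", call. = FALSE)
  dstate <- numeric(length(state))
  if (n == 0L) return(dstate)
  h <- hill_factor(state[r_idx], params$K)
  pol <- attr(genes, "polymerase")
  p_pol <- if (is.na(pol)) 1 else state[genes$p_idx[match(pol, genes$gene)]]
  d <- state[genes$d_idx]
  m <- state[genes$m_idx]
  p <- state[genes$p_idx]
  tx <- params$alpha * d * ifelse(genes$requires_t7, p_pol, 1) * h
  tl <- params$beta * m * h
  dstate[genes$m_idx] <- tx - params$delta_m * m
  dstate[genes$p_idx] <- tl - params$delta_p * p
  dstate[r_idx] <- -(sum(tx) + sum(tl))
  dstate
}
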