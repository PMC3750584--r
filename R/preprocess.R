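# IC50 -> sensitivity scaling and log-scale EC50-window target binarization.

#' Binarization configuration
#'
#' Parameters of the log-scale EC50 window used to decide which targets a
#' drug functionally inhibits.  A target j of drug i is called a hit when
#' `alpha * log(IC50_i) <= log(EC50_ij) <= beta * log(IC50_i)` (logs in
#' `log_base` after flooring all concentrations at `floor_nM`).  The lower
#' bound `alpha` is usually 0 so that strong (low-EC50) side targets stay in
#' scope; `beta` stretches the window above the IC50 and should stay a small
#' constant — wide windows admit interactions far too weak to matter at
#' achievable doses.
#'
#' Concentrations are floored at `floor_nM` (just above 1 nM) before taking
#' logs so every log is strictly positive; sub-nanomolar values would make
#' `alpha * log(IC50) <= beta * log(IC50)` flip direction.
#'
#' @param alpha lower window multiplier, `0 <= alpha < beta`.
#' @param beta upper window multiplier.
#' @param log_base base of the logarithms (default 10).
#' @param floor_nM positive flooring concentration in nM.
#' @return object of class `binarization_config`.
#' @export
binarization_config <- function(alpha = 0, beta = 2, log_base = 10,
                                floor_nM = 1.01) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha >= 0, beta > alpha,
            log_base > 0, floor_nM > 1)
  structure(list(alpha = alpha, beta = beta, log_base = log_base,
                 floor_nM = floor_nM), class = "binarization_config")
}

#' Convert IC50 values to continuous sensitivity scores
#'
#' Maps a drug's screen IC50 to a score y in [0,1]: y = 1 when the IC50 is
#' below the maximum clinically achievable dose Cmax, y = 0 when the IC50
#' was not reached within the screened range (or is at/above MaxDose), and a
#' log-linear decay in between:
#' \deqn{y = c (1 - \log(IC50)/\log(MaxDose)), \quad Cmax \le IC50 \le MaxDose.}
#'
#' With `continuity_fix = TRUE` (the default) the constant is
#' `c = 1 / (1 - log(Cmax)/log(MaxDose))`, which makes the decay continuous
#' with the first branch (y(Cmax) = 1, y(MaxDose) = 0).  Setting
#' `continuity_fix = FALSE` uses `c = 1 - log(Cmax)/log(MaxDose)` instead,
#' which leaves a jump at IC50 = Cmax; it is kept only for compatibility
#' with formulations that quote that constant.
#'
#' @param ic50 numeric vector of IC50 values in nM; `NA` = not reached.
#' @param cmax maximum achievable clinical dose(s), nM.
#' @param maxdose maximum screened dose(s), nM.
#' @param continuity_fix logical; see Details.
#' @param floor_nM concentration floor applied before logs.
#' @return numeric vector of sensitivity scores in [0,1].
#' @examples
#' scale_sensitivity(10, cmax = 100, maxdose = 10000)    # 1: below Cmax
#' scale_sensitivity(10000, cmax = 100, maxdose = 10000) # 0: at MaxDose
#' scale_sensitivity(1000, cmax = 100, maxdose = 10000)  # interior decay
#' @export
scale_sensitivity <- function(ic50, cmax, maxdose, continuity_fix = TRUE,
                              floor_nM = 1.01) {
  n <- max(length(ic50), length(cmax), length(maxdose))
  ic50 <- rep_len(ic50, n); cmax <- rep_len(cmax, n)
  maxdose <- rep_len(maxdose, n)
  if (any(cmax >= maxdose)) stop("cmax must be < maxdose")
  if (any(cmax <= 0) || any(maxdose <= 0)) stop("doses must be positive")
  cmax <- pmax(cmax, floor_nM); maxdose <- pmax(maxdose, floor_nM)
  ratio <- log(cmax) / log(maxdose)
  cc <- if (continuity_fix) 1 / (1 - ratio) else 1 - ratio
  x <- pmax(ic50, floor_nM)
  y <- cc * (1 - log(x) / log(maxdose))
  y[!is.na(ic50) & ic50 < cmax] <- 1
  y[is.na(ic50) | ic50 >= maxdose] <- 0
  pmin(pmax(y, 0), 1)
}

#' Binarize one drug's targets through the EC50 window
#'
#' @param ec50 named numeric vector of the drug's EC50s (nM) over the
#'   targets it interacts with.
#' @param ic50 the drug's screen IC50 in nM; `NA` (not reached) falls back
#'   to `maxdose` so that failing drugs still contribute their achievable
#'   inhibition profile as negative evidence.
#' @param cfg a [binarization_config()].
#' @param universe character vector of all target names.
#' @param maxdose maximum screened dose, used as the window anchor when the
#'   IC50 was not reached.
#' @return logical vector over `universe`: `TRUE` = target hit (the DTIP).
#' @examples
#' binarize_targets(c(A = 5, B = 5000), ic50 = 10,
#'                  cfg = binarization_config(alpha = 0, beta = 2),
#'                  universe = c("A", "B", "C"))
#' @export
binarize_targets <- function(ec50, ic50, cfg = binarization_config(),
                             universe = names(ec50), maxdose = NULL) {
  hit <- rep(FALSE, length(universe))
  names(hit) <- universe
  if (length(ec50) == 0L) return(hit)
  anchor <- if (is.na(ic50)) {
    if (is.null(maxdose)) stop("maxdose needed to binarize a drug whose IC50 was not reached")
    maxdose
  } else ic50
  lb <- log(max(anchor, cfg$floor_nM), base = cfg$log_base)
  le <- log(pmax(ec50, cfg$floor_nM), base = cfg$log_base)
  inside <- (le >= cfg$alpha * lb) & (le <= cfg$beta * lb)
  hit[names(ec50)[inside]] <- TRUE
  hit
}

#' Binarize a whole screen and score its drugs
#'
#' Applies [scale_sensitivity()] and [binarize_targets()] to every drug of a
#' [screen_dataset()].  Drugs whose EC50 window captures no target are
#' flagged `excluded` — they carry no usable inhibition information and are
#' dropped before target selection.  With `rescale = TRUE` (default) the
#' sensitivity scores are additionally min-max rescaled to span [0,1] within
#' the culture, so that the most effective screened drug anchors the top of
#' the scale.
#'
#' @param screen a `screen_dataset`.
#' @param cfg a [binarization_config()].
#' @param rescale logical; per-culture min-max rescaling of scores.
#' @param continuity_fix passed to [scale_sensitivity()].
#' @return object of class `binarized_screen`: list with `drug` (ids),
#'   `y` (scores), `dtip` (logical drugs x targets matrix), `excluded`
#'   (logical), `universe`, `culture_id`.
#' @export
binarize_screen <- function(screen, cfg = binarization_config(),
                            rescale = TRUE, continuity_fix = TRUE) {
  stopifnot(inherits(screen, "screen_dataset"))
  d <- screen$drugs
  y <- scale_sensitivity(d$ic50, d$cmax, d$maxdose,
                         continuity_fix = continuity_fix,
                         floor_nM = cfg$floor_nM)
  if (rescale && diff(range(y)) > 0)
    y <- (y - min(y)) / (max(y) - min(y))
  dtip <- t(vapply(seq_len(nrow(d)), function(i) {
    binarize_targets(screen$profiles[[d$drug[i]]], d$ic50[i], cfg,
                     universe = screen$universe, maxdose = d$maxdose[i])
  }, logical(length(screen$universe))))
  rownames(dtip) <- d$drug
  structure(list(drug = d$drug, y = y, dtip = dtip,
                 excluded = rowSums(dtip) == 0L,
                 universe = screen$universe,
                 culture_id = screen$culture_id),
            class = "binarized_screen")
}

#' @export
print.binarized_screen <- function(x, ...) {
  cat(sprintf("binarized_screen '%s': %d drugs, %d targets, %d excluded (no target in window)\n",
              x$culture_id, length(x$drug), length(x$universe),
              sum(x$excluded)))
  invisible(x)
}
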