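## Identified causal effects for an exposure contrast.
##
## Under the linear mediation model without exposure-mediator interaction,
## and under SUTVA, consistency, sequential ignorability and positivity, the
## average causal mediation effect (ACME) and the average natural direct
## effect (ANDE) for a contrast (x, x') have closed forms in the regression
## coefficients:
##   ACME  = betaM' gammaX' (x - x')
##   ANDE  = betaX' (x - x')
##   total = ACME + ANDE = (betaX + gammaX betaM)' (x - x').
## These assumptions are untestable from the data; each estimate carries a
## structured assumptions report rather than a pretended check.

#' Estimated causal effects for one exposure contrast
#'
#' @slot contrastX,contrastXprime the two exposure settings (k-vectors).
#' @slot acme r-vector average causal mediation effect.
#' @slot ande r-vector average natural direct effect.
#' @slot total r-vector total effect (= acme + ande exactly).
#' @slot assumptions character vector naming the identification assumptions
#'   under which the causal reading is valid.
#' @export
setClass("EffectEstimates",
  representation(contrastX = "numeric", contrastXprime = "numeric",
                 acme = "numeric", ande = "numeric", total = "numeric",
                 assumptions = "character"))

setValidity("EffectEstimates", function(object) {
  if (max(abs(object@total - (object@acme + object@ande))) > 1e-12 *
      (1 + max(abs(object@total))))
    "total must equal acme + ande" else TRUE
})

setMethod("show", "EffectEstimates", function(object) {
  cat("EffectEstimates for contrast x vs x':\n")
  print(data.frame(acme = signif(object@acme, 4),
                   ande = signif(object@ande, 4),
                   total = signif(object@total, 4)))
  cat("Causal reading requires:", paste(object@assumptions, collapse = "; "),
      "\n")
})

.identificationAssumptions <- c(
  "SUTVA (no interference, no hidden treatment versions)",
  "consistency (observed outcome equals potential outcome at the received exposure)",
  "sequential ignorability given Z (exposure independent of potential mediators/outcomes; mediators independent of potential outcomes given exposure and Z)",
  "positivity of exposure and mediator levels",
  "immaterial mediator component carries no outcome information given the material part, exposure and Z")

#' Compute ACME, ANDE and the total effect for an exposure contrast
#'
#' @param fit an \linkS4class{EsplsmFit}.
#' @param x,xprime exposure settings (k-vectors); effects are linear in
#'   \code{x - xprime}.
#' @return An \linkS4class{EffectEstimates}; \code{total = acme + ande}
#'   holds exactly.
#' @examples
#' des <- makeDesign("main", seedDesign = 1)
#' fit <- fitEsplsm(simulateDataset(des, n = 300, seedData = 3),
#'                  d = 1, lambda = "auto", seed = 3)
#' causalEffects(fit, x = 1, xprime = 0)
#' @export
causalEffects <- function(fit, x, xprime) {
  stopifnot(is(fit, "EsplsmFit"))
  k <- nrow(fit@betaX)
  x <- as.numeric(x); xprime <- as.numeric(xprime)
  if (length(x) != k || length(xprime) != k)
    stop(sprintf("contrast vectors must have length k = %d", k),
         call. = FALSE)
  dx <- x - xprime
  acme <- as.numeric(crossprod(fit@betaM, crossprod(fit@gammaX, dx)))
  ande <- as.numeric(crossprod(fit@betaX, dx))
  new("EffectEstimates", contrastX = x, contrastXprime = xprime,
      acme = acme, ande = ande, total = acme + ande,
      assumptions = .identificationAssumptions)
}
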