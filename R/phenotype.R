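#' Construct a GerminationRecord
#'
#' Supply either the full daily counts `Gt` (days 1..8 from sowing; a
#' seed counts as germinated the first day its germ exceeds 1.5 cm) or
#' only the summary counts `m1`/`m2`.
#'
#' @param M total seeds tested.
#' @param Gt numeric length-8 daily germinated counts, or NULL.
#' @param m1 seeds germinated within 3 days (derived from Gt if given).
#' @param m2 seeds germinated within 8 days (derived from Gt if given).
#' @param S seedling (root) mass scale after 8 days; NA when unmeasured.
#' @return a [GerminationRecord].
#' @examples
#' germinationRecord(M = 80, m2 = 77)           # summary only
#' germinationRecord(M = 10, Gt = c(2, 5, 1, 1, 0, 0, 0, 0), S = 1.6)
#' @export
germinationRecord <- function(M, Gt = NULL, m1 = NA, m2 = NA, S = NA_real_) {
  if (!is.null(Gt)) {
    stopifnot(length(Gt) == 8L)
    m2 <- sum(Gt)
    m1 <- sum(Gt[1:3])
  } else {
    Gt <- rep(NA_real_, 8L)
  }
  new("GerminationRecord", M = as.integer(M), Gt = as.numeric(Gt),
      m1 = as.integer(m1), m2 = as.integer(m2), S = as.numeric(S))
}

#' Compute the six germination vigor indices
#'
#' With daily counts Gt on days Dt = 1..8 and M seeds tested:
#' \deqn{GP = 100 m_1 / M,\quad GE = 100 m_2 / M,\quad
#'       GI = \sum_t G_t / D_t,\quad MGT = \sum_t G_t D_t / \sum_t G_t,}
#' \deqn{VI = GI \cdot S,\quad SVI = (GP/100) \cdot S.}
#' GP and GE are percentages. SVI uses GP as a fraction: the seedling
#' mass scale S is of order 1, and published SVI values of order 0.3-1.6
#' are only consistent with the fractional convention. When nothing
#' germinated MGT is undefined (`mgtDefined = FALSE`, MGT = NA).
#' Indices needing the daily profile (GI, MGT) or S (VI, SVI) are NA when
#' those inputs were not recorded.
#'
#' @param record a [GerminationRecord].
#' @param days day numbers Dt (default 1..8, 1-based from sowing).
#' @return a [VigorIndices].
#' @examples
#' vigorIndices(germinationRecord(M = 80, m2 = 77))@GE   # 96.25
#' @export
vigorIndices <- function(record, days = 1:8) {
  stopifnot(is(record, "GerminationRecord"), length(days) == 8L)
  validObject(record)
  M <- record@M
  GP <- if (is.na(record@m1)) NA_real_ else 100 * record@m1 / M
  GE <- if (is.na(record@m2)) NA_real_ else 100 * record@m2 / M
  if (all(is.na(record@Gt))) {
    GI <- NA_real_; MGT <- NA_real_
    mgtDefined <- !is.na(record@m2) && record@m2 > 0
  } else {
    GI <- sum(record@Gt / days)
    tot <- sum(record@Gt)
    mgtDefined <- tot > 0
    MGT <- if (mgtDefined) sum(record@Gt * days) / tot else NA_real_
  }
  S <- record@S
  new("VigorIndices",
      GP = GP, GE = GE, GI = GI, MGT = MGT,
      VI = if (is.na(S)) NA_real_ else GI * S,
      SVI = if (is.na(S) || is.na(GP)) NA_real_ else (GP / 100) * S,
      mgtDefined = mgtDefined)
}

setMethod("show", "VigorIndices", function(object) {
  cat(sprintf(
    "VigorIndices: GP %.2f%%  GE %.2f%%  GI %.2f  MGT %s  VI %.2f  SVI %.2f\n",
    object@GP, object@GE, object@GI,
    if (object@mgtDefined) sprintf("%.2f d", object@MGT) else "undefined",
    object@VI, object@SVI))
})

#' Vigor-index table for several groups
#'
#' @param records named list of [GerminationRecord]s (e.g. A0..A4).
#' @return data.frame with one row per group and columns GP, GE, GI,
#'   MGT, VI, SVI (GP/GE in percent).
#' @export
vigorIndexTable <- function(records) {
  rows <- lapply(records, function(r) {
    vi <- vigorIndices(r)
    data.frame(GP = vi@GP, GE = vi@GE, GI = vi@GI, MGT = vi@MGT,
               VI = vi@VI, SVI = vi@SVI)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(records)
  out
}

#' SOD activity from an NBT photoreduction assay
#'
#' One unit of superoxide dismutase activity is the amount inhibiting
#' nitroblue-tetrazolium photoreduction by 50 percent, giving
#' \deqn{SOD = \frac{[(A_0 - A_b) - (A_s - A_b)] \cdot V_T}
#'                  {\tfrac{1}{2} (A_0 - A_b) \cdot W \cdot V_s}}
#' in U per gram fresh weight.
#'
#' @param Ab dark-control absorbance at 560 nm.
#' @param A0 light-control absorbance (must exceed `Ab`).
#' @param As sample absorbance.
#' @param VT total enzyme-extract volume (mL).
#' @param Vs extract volume measured (mL), 0 < Vs <= VT.
#' @param W sample fresh weight (g).
#' @return SOD activity in U/g FW.
#' @examples
#' sodActivity(Ab = 0.05, A0 = 0.85, As = 0.45, VT = 5, Vs = 0.1, W = 1)
#' @export
sodActivity <- function(Ab, A0, As, VT, Vs, W) {
  if (!(A0 > Ab)) stop("light control A0 must exceed dark control Ab")
  if (!(Vs > 0 && VT >= Vs)) stop("need 0 < Vs <= VT")
  if (!(W > 0)) stop("fresh weight W must be positive")
  ((A0 - Ab) - (As - Ab)) * VT / (0.5 * (A0 - Ab) * W * Vs)
}
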