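# Core domain containers and the annual mass-balance bookkeeping.
#
# Nutrient pools are carried as elemental N, P, K and organic C, in kg/ha of
# the managed soil layer. Bulk density, coarse fragments and layer depth enter
# only when converting between concentrations (mg/kg, as mapped) and areal
# stocks (kg/ha); the year-to-year ledger is a plain sum in kg/ha so mass
# conservation is exact.

NUTRIENTS <- c("n", "p", "k", "c")

#' Nutrient pathways and the nutrients each may carry
#'
#' Five input pathways (IN1 inorganic fertilizer, IN2 decomposition of manure
#' and residues, IN3 biological N fixation, IN4 sediment deposition, IN5
#' atmospheric deposition) and five output pathways (OUT1 harvested grain,
#' OUT2 removed residues, OUT3 erosion, OUT4 leaching, OUT5 gaseous losses
#' plus organic-matter degradation C). A pathway that does not carry a
#' nutrient must hold zero for it.
#'
#' @format named list: pathway -> character vector of carried nutrients
#'   (subset of `n`, `p`, `k`, `c`).
#' @export
PATHWAY_NUTRIENTS <- list(
  IN1  = c("n", "p"),
  IN2  = c("n", "p", "k", "c"),
  IN3  = "n",
  IN4  = c("n", "p", "k", "c"),
  IN5  = c("n", "p", "k"),
  OUT1 = c("n", "p", "k"),
  OUT2 = c("n", "p", "k"),
  OUT3 = c("n", "p", "k", "c"),
  OUT4 = c("n", "k"),
  OUT5 = c("n", "c")
)

#' Elemental conversion factors for fertilizer oxide grades
#'
#' Mass of elemental P per unit P2O5 and elemental K per unit K2O.
#' @export
P2O5_TO_P <- 0.436

#' @rdname P2O5_TO_P
#' @export
K2O_TO_K <- 0.830

#' Soil nutrient stock of the managed layer
#'
#' Vectorised container: each field may be a vector (one element per plot or
#' pixel). Pools are kg/ha of elemental N, P, K and organic C.
#'
#' @param n,p,k,soc nutrient pools, kg/ha; must be non-negative.
#' @param rho bulk density, t/m3 (> 0).
#' @param cf coarse-fragment volumetric fraction in `[0, 1)`.
#' @param depth managed layer thickness, m (> 0); default 0.10 m, the hand-hoe
#'   ridge layer into which fertilizer and manure are placed.
#' @return object of class `soil_stock` (a list of parallel vectors).
#' @export
#' @examples
#' s <- soil_stock(n = 1000, p = 300, k = 800, soc = 20000)
soil_stock <- function(n, p, k, soc, rho = 1.3, cf = 0, depth = 0.10) {
  len <- max(length(n), length(p), length(k), length(soc))
  out <- list(
    n = rep_len(as.numeric(n), len), p = rep_len(as.numeric(p), len),
    k = rep_len(as.numeric(k), len), soc = rep_len(as.numeric(soc), len),
    rho = rep_len(as.numeric(rho), len), cf = rep_len(as.numeric(cf), len),
    depth = rep_len(as.numeric(depth), len)
  )
  with(out, {
    if (any(n < 0 | p < 0 | k < 0 | soc < 0)) stop("soil_stock: pools must be >= 0")
    if (any(cf < 0 | cf >= 1)) stop("soil_stock: cf must be in [0, 1)")
    if (any(rho <= 0)) stop("soil_stock: rho must be > 0")
    if (any(depth <= 0)) stop("soil_stock: depth must be > 0")
  })
  structure(out, class = "soil_stock")
}

#' @export
print.soil_stock <- function(x, ...) {
  cat("<soil_stock> ", length(x$n), " unit(s); mean pools kg/ha: N ",
      round(mean(x$n), 1), ", P ", round(mean(x$p), 1), ", K ",
      round(mean(x$k), 1), ", SOC ", round(mean(x$soc), 1), "\n", sep = "")
  invisible(x)
}

#' One year's nutrient flow along one pathway
#'
#' Amounts are kg/ha/yr; components a pathway does not carry (see
#' [PATHWAY_NUTRIENTS]) must be zero. Fields may be vectors (per plot).
#'
#' @param pathway one of `IN1`..`IN5`, `OUT1`..`OUT5`.
#' @param n,p,k,c nutrient amounts, kg/ha/yr, non-negative.
#' @return object of class `flow_vector`.
#' @export
flow_vector <- function(pathway, n = 0, p = 0, k = 0, c = 0) {
  pathway <- match.arg(pathway, names(PATHWAY_NUTRIENTS))
  len <- max(length(n), length(p), length(k), length(c))
  comp <- list(n = rep_len(as.numeric(n), len), p = rep_len(as.numeric(p), len),
               k = rep_len(as.numeric(k), len), c = rep_len(as.numeric(c), len))
  for (nut in NUTRIENTS) {
    if (any(comp[[nut]] < 0))
      stop("flow_vector: ", pathway, " ", nut, " must be >= 0")
    if (!nut %in% PATHWAY_NUTRIENTS[[pathway]] && any(comp[[nut]] != 0))
      stop("flow_vector: pathway ", pathway, " does not carry ", toupper(nut))
  }
  structure(c(list(pathway = pathway), comp), class = "flow_vector")
}

#' @export
print.flow_vector <- function(x, ...) {
  cat("<flow_vector ", x$pathway, "> mean kg/ha/yr: N ", round(mean(x$n), 2),
      ", P ", round(mean(x$p), 2), ", K ", round(mean(x$k), 2),
      ", C ", round(mean(x$c), 2), "\n", sep = "")
  invisible(x)
}

#' Convert a soil nutrient concentration to an areal stock
#'
#' `stock = conc * rho * depth * (1 - cf) * 10`: the fine-earth mass of a
#' layer of thickness `depth` over one hectare, times the mass fraction.
#' Coarse fragments reduce the fine-earth mass, hence the `(1 - cf)` factor.
#'
#' @param conc concentration, mg/kg fine earth; non-negative.
#' @param rho bulk density, t/m3.
#' @param cf coarse-fragment volumetric fraction in `[0, 1)`.
#' @param depth layer thickness, m.
#' @return stock in kg/ha.
#' @export
#' @examples
#' concentration_to_stock(100, rho = 1.3, cf = 0, depth = 0.10) # 130 kg/ha
concentration_to_stock <- function(conc, rho, cf = 0, depth = 0.10) {
  if (any(!is.finite(conc)) || any(conc < 0)) stop("conc must be finite and >= 0")
  if (any(rho <= 0) || any(depth <= 0)) stop("rho and depth must be > 0")
  if (any(cf < 0 | cf >= 1)) stop("cf must be in [0, 1)")
  conc * rho * depth * (1 - cf) * 10
}

#' @rdname concentration_to_stock
#' @param stock areal stock, kg/ha.
#' @export
stock_to_concentration <- function(stock, rho, cf = 0, depth = 0.10) {
  if (any(rho <= 0) || any(depth <= 0)) stop("rho and depth must be > 0")
  if (any(cf < 0 | cf >= 1)) stop("cf must be in [0, 1)")
  stock / (rho * depth * (1 - cf) * 10)
}

#' Annual mass-balance update of soil stocks
#'
#' `X_{t+1} = X_t + sum(IN_X) - sum(OUT_X)` per nutrient, with pools floored
#' at zero and the clipped deficit logged as a positive magnitude, so the
#' full ledger `X_{t+1} - X_t - clipped = sum(IN) - sum(OUT)` always closes
#' exactly.
#'
#' @param stock a [soil_stock].
#' @param inflows list of [flow_vector]s with pathways among `IN1`..`IN5`.
#' @param outflows list of [flow_vector]s with pathways among `OUT1`..`OUT5`.
#' @return list with elements `stock` (updated [soil_stock]) and `clipped`
#'   (data.frame of per-unit clipped deficits for `n`, `p`, `k`, `soc`).
#' @export
update_soil_stock <- function(stock, inflows, outflows) {
  stopifnot(inherits(stock, "soil_stock"))
  check_side <- function(flows, side) {
    for (f in flows) {
      if (!inherits(f, "flow_vector")) stop("flows must be flow_vector objects")
      if (!startsWith(f$pathway, side))
        stop("pathway ", f$pathway, " not allowed among ", side, " flows")
    }
  }
  check_side(inflows, "IN")
  check_side(outflows, "OUT")
  len <- length(stock$n)
  sum_side <- function(flows, nut) {
    tot <- numeric(len)
    for (f in flows) tot <- tot + rep_len(f[[nut]], len)
    tot
  }
  pools <- c(n = "n", p = "p", k = "k", soc = "c")
  clipped <- data.frame(n = numeric(len), p = numeric(len),
                        k = numeric(len), soc = numeric(len))
  new <- stock
  for (pool in names(pools)) {
    nut <- pools[[pool]]
    raw <- stock[[pool]] + sum_side(inflows, nut) - sum_side(outflows, nut)
    clipped[[pool]] <- pmax(0, -raw)
    new[[pool]] <- pmax(0, raw)
  }
  list(stock = new, clipped = clipped)
}

#' Built-in fertilizer product grades
#'
#' Mass fractions of N, P2O5 and K2O for the grades common in the Malawi
#' maize system: urea (46-0-0), DAP (18-46-0) and the basal compound
#' NPK 23:21:0+4S.
#'
#' @return data.frame with columns `name`, `n_frac`, `p2o5_frac`, `k2o_frac`.
#' @export
fertilizer_products <- function() {
  data.frame(
    name = c("urea", "dap", "npk_23_21_0"),
    n_frac = c(0.46, 0.18, 0.23),
    p2o5_frac = c(0, 0.46, 0.21),
    k2o_frac = c(0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Convert a fertilizer application to an IN1 nutrient flow
#'
#' N is taken at the product's N fraction; P is converted from the P2O5
#' fraction by [P2O5_TO_P]. The inorganic-fertilizer pathway carries N and P
#' only, so K-bearing grades are rejected. The pre-conversion oxide masses
#' are attached as attributes `p2o5` and `k2o`.
#'
#' @param amount product amount, kg/ha (vector allowed); non-negative.
#' @param product a grade name known to [fertilizer_products()], or a list /
#'   one-row data.frame with fields `name`, `n_frac`, `p2o5_frac`, `k2o_frac`.
#' @return a [flow_vector] with pathway `IN1`.
#' @export
#' @examples
#' f <- product_to_nutrients(87, "dap")
#' attr(f, "p2o5") # 40.02 kg P2O5 / ha
product_to_nutrients <- function(amount, product) {
  if (any(amount < 0)) stop("amount must be >= 0")
  if (is.character(product)) {
    grades <- fertilizer_products()
    i <- match(product, grades$name)
    if (is.na(i))
      stop("unknown fertilizer product '", product, "'; known grades: ",
           paste(grades$name, collapse = ", "))
    product <- grades[i, ]
  }
  if (product$k2o_frac > 0)
    stop("the inorganic-fertilizer pathway (IN1) carries N and P only; ",
         "grade '", product$name, "' contains K2O")
  fv <- flow_vector("IN1",
                    n = amount * product$n_frac,
                    p = amount * product$p2o5_frac * P2O5_TO_P)
  attr(fv, "p2o5") <- amount * product$p2o5_frac
  attr(fv, "k2o") <- amount * product$k2o_frac
  fv
}
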