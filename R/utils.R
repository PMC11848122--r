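#' @keywords internal
#' @importFrom mgcv gam s predict.gam
#' @importFrom stats setNames rnorm runif rlnorm rpois dist aggregate lm anova residuals df.residual pf model.matrix optim
#' @importFrom utils read.csv write.csv capture.output packageVersion
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded functions never clobber the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(abs(seed) %% 2147483629))
  force(code)
}

# deterministic sub-stream seeds, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((abs(as.double(seed)) * 48271 + 7919 * abs(as.double(offset))) %% 2147483587)
}

#' Canonical trait, trait-group and feeding-mode vocabularies
#'
#' The 13 community traits in their fixed column order: five energy
#' acquisition traits (oral gape surface `Osf`, oral gape shape `Osh`, oral
#' gape position `Ops`, protrusion `Pro`, eye size `ES`), five locomotion
#' traits (eye position `EP`, body transverse surface `Bsf`, body transverse
#' shape `Bsh`, pectoral fin position `Pfp`, caudal peduncle throttling
#' `Cpt`), and three nutrient recycling traits (ammonium excretion `NH4`,
#' phosphate excretion `PO4`, and their ratio `N_P`).
#'
#' @return `trait_names()`: character vector of 13 trait codes.
#' @export
trait_names <- function() {
  c("Osf", "Osh", "Ops", "Pro", "ES",
    "EP", "Bsf", "Bsh", "Pfp", "Cpt",
    "NH4", "PO4", "N_P")
}

#' @rdname trait_names
#' @return `trait_groups()`: named character vector mapping each trait to
#'   its functional role (`energy`, `locomotion`, `nutrient`).
#' @export
trait_groups <- function() {
  stats::setNames(
    c(rep("energy", 5), rep("locomotion", 5), rep("nutrient", 3)),
    trait_names()
  )
}

#' @rdname trait_names
#' @return `feeding_modes()`: the four trophic feeding modes.
#' @export
feeding_modes <- function() {
  c("detritivore", "planktivore", "hunting_meiofauna", "hunting_macrofauna")
}

#' @rdname trait_names
#' @return `nutrient_traits()`: the three family-level nutrient traits.
#' @export
nutrient_traits <- function() c("NH4", "PO4", "N_P")

stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
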