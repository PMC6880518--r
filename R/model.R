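#' Create an empty model
#'
#' A model bundles species definitions, reaction rules, global force fields and
#' contact settings. It is an environment with reference semantics: the
#' `register_*` / `add_*` helpers mutate it in place and return their argument
#' invisibly, so models can be built up imperatively.
#'
#' @param dimension spatial dimension, 2 or 3.
#' @param contact logical; if `FALSE`, non-reactive Hertz contact forces are
#'   disabled globally (used e.g. for free-diffusion reference scenarios).
#' @param stiffness_exponent exponent `p` of the contact law `F ~ d^p`. The
#'   default 1.5 is the Hertz law; any positive polynomial exponent is accepted
#'   for sparse systems where the exact elastic dynamics do not matter.
#' @return an object of class `nf_model`.
#' @export
new_model <- function(dimension = 3, contact = TRUE, stiffness_exponent = 1.5) {
  stopifnot(dimension %in% c(2L, 3L), stiffness_exponent > 0)
  m <- new.env(parent = emptyenv())
  m$dimension <- as.integer(dimension)
  m$species <- list()
  m$rules0 <- list()
  m$rules1 <- list()   # first-order, including division rules
  m$rules2 <- list()   # bimolecular (fuse/transform/nest/unnest)
  m$fields <- list()
  m$contact <- isTRUE(contact)
  m$stiffness_exponent <- stiffness_exponent
  m$estar_cache <- list()
  class(m) <- "nf_model"
  m
}

.nf_kind_of <- function(x) {
  switch(typeof(x),
    double = "number", integer = "integer", logical = "boolean",
    character = "string",
    stop("unsupported attribute kind: ", typeof(x), call. = FALSE))
}

#' Register a species
#'
#' Species are named classes of particles sharing an attribute schema and
#' physical defaults. Every particle carries at least a (positive) radius and a
#' density; the attribute schema is given as a named list of default values
#' whose types (number / integer / boolean / string) fix the schema kinds.
#'
#' @param model an `nf_model`.
#' @param name unique species name.
#' @param radius default radius (m), > 0.
#' @param density mass density (kg/m^3), > 0.
#' @param attributes named list of attribute defaults; types define the schema.
#' @param interior_viscosity dynamic viscosity (Pa.s) experienced by particles
#'   contained in a particle of this species, or `NULL` to inherit from the
#'   enclosing compartment (ultimately the medium).
#' @param young_modulus Young's modulus E (Pa) for Hertz contact.
#' @param poisson_ratio Poisson's ratio, in [0, 0.5).
#' @param mobile logical; immobile species are spatially anchored (no
#'   integration, no thermal force) except while participating in a division.
#' @return the `nf_species` definition, invisibly.
#' @export
register_species <- function(model, name, radius, density = 1000,
                             attributes = list(), interior_viscosity = NULL,
                             young_modulus = 1e3, poisson_ratio = 0.3,
                             mobile = TRUE) {
  stopifnot(inherits(model, "nf_model"), is.character(name), length(name) == 1L)
  if (name %in% names(model$species))
    stop("species '", name, "' is already registered", call. = FALSE)
  if (!is.numeric(radius) || radius <= 0) stop("default_radius must be > 0", call. = FALSE)
  if (!is.numeric(density) || density <= 0) stop("default_density must be > 0", call. = FALSE)
  if (young_modulus <= 0) stop("elastic_modulus must be > 0", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must be in [0, 0.5)", call. = FALSE)
  if (length(attributes) && (is.null(names(attributes)) ||
      anyDuplicated(names(attributes)) || any(names(attributes) == "")))
    stop("attribute schema names must be unique and non-empty", call. = FALSE)
  if (!is.null(interior_viscosity))
    stopifnot(is.numeric(interior_viscosity), interior_viscosity > 0)
  kinds <- vapply(attributes, .nf_kind_of, character(1))
  sp <- list(name = name, radius = radius, density = density,
             attributes = attributes, kinds = kinds,
             interior_viscosity = interior_viscosity,
             young_modulus = young_modulus, poisson_ratio = poisson_ratio,
             mobile = isTRUE(mobile))
  class(sp) <- "nf_species"
  model$species[[name]] <- sp
  model$estar_cache <- list()
  invisible(sp)
}

.nf_check_species <- function(model, name, what = "species") {
  if (!name %in% names(model$species))
    stop("unknown ", what, ": '", name, "'", call. = FALSE)
  name
}

#' Rule builders
#'
#' Declarative reaction descriptions mirroring the rule notation of the
#' modeling layer. Zeroth-order rules create particles at a global rate;
#' first-order rules fire per matching particle with an arbitrary,
#' attribute/content-dependent propensity; division rules are first-order rules
#' whose product is a continuous, force-driven compartment fission; bimolecular
#' rules are mediated by a constant reactive force with energy barrier `W` over
#' a required overlap `d_star`.
#'
#' Rate arguments may be a plain number (constant propensity, evaluated on a
#' fast vectorised path) or a function `function(state, id) -> 1/s` evaluated
#' per particle per step. Post-reaction functions receive the state and the ids
#' involved and may mutate attributes, retarget radii, spawn or remove
#' particles via the `p_*` accessors.
#'
#' @param product,species,species_a,species_b species names.
#' @param rate propensity (1/s): number or `function(state, id)`; for
#'   zeroth-order rules `function(state)`.
#' @param placement where zeroth-order products appear: uniformly in the
#'   domain, uniformly inside a particle of `parent_species`, or barely
#'   touching the surface of a particle of `parent_species`.
#' @param parent_species species providing the spatial context for
#'   `"inside"`/`"surface"` placement.
#' @param attrs attribute overrides for created particles.
#' @param radius radius override for created particles (m).
#' @param post post-reaction function (the "after" function), see Details.
#' @param predicate optional `function(state, id) -> logical` gating the rule.
#' @param a_division division acceleration (m/s^2), > 0.
#' @param split optional `function(state, id, content_ids) -> integer vector`
#'   of 1/2 assignments; default independent fair coin per content particle.
#' @param attrs1,attrs2 optional `function(state, id) -> named list` producing
#'   the children's attribute maps (default: inherit the parent's values).
#' @param radius_fractions length-2 numeric: children target radii as fractions
#'   of the parent radius; the default `2^(-1/3)` halves the volume of each.
#' @param kind bimolecular kind: `"fuse"`, `"transform"`, `"nest"`, `"unnest"`.
#' @param d_star required overlap depth (m), > 0; alternatively give
#'   `d_star_frac`, a fraction of the smaller radius of the pair, resolved per
#'   pair at contact time.
#' @param d_star_frac see `d_star`.
#' @param W energy barrier (J), >= 0. `W = 0` is the diffusion-limited case.
#' @param context optional containment context: a species name (both reactants
#'   must live inside a particle of that species) or `"top"` (medium level).
#' @return a rule object; add it to a model with [add_rule()].
#' @name rules
NULL

#' @rdname rules
#' @export
rule_zeroth <- function(product, rate,
                        placement = c("random_in_domain", "inside", "surface"),
                        parent_species = NULL, radius = NULL, attrs = list()) {
  placement <- match.arg(placement)
  if (placement != "random_in_domain" && is.null(parent_species))
    stop("placement '", placement, "' needs a parent_species", call. = FALSE)
  stopifnot(is.numeric(rate) || is.function(rate))
  if (is.numeric(rate) && rate < 0) stop("rate must be >= 0", call. = FALSE)
  structure(list(order = 0L, product = product, rate = rate,
                 placement = placement, parent_species = parent_species,
                 radius = radius, attrs = attrs),
            class = c("nf_rule0", "nf_rule"))
}

#' @rdname rules
#' @export
rule_first <- function(species, rate, post, predicate = NULL) {
  stopifnot(is.numeric(rate) || is.function(rate), is.function(post))
  if (is.numeric(rate) && rate < 0) stop("rate must be >= 0", call. = FALSE)
  structure(list(order = 1L, kind = "plain", species = species, rate = rate,
                 post = post, predicate = predicate),
            class = c("nf_rule1", "nf_rule"))
}

#' @rdname rules
#' @export
rule_divide <- function(species, rate, a_division, split = NULL,
                        attrs1 = NULL, attrs2 = NULL,
                        radius_fractions = c(2^(-1 / 3), 2^(-1 / 3)),
                        predicate = NULL) {
  stopifnot(is.numeric(rate) || is.function(rate))
  if (!is.numeric(a_division) || a_division <= 0)
    stop("a_division must be > 0 (a division with a = 0 never completes)",
         call. = FALSE)
  stopifnot(length(radius_fractions) == 2L, all(radius_fractions > 0))
  structure(list(order = 1L, kind = "divide", species = species, rate = rate,
                 a_division = a_division, split = split,
                 attrs1 = attrs1, attrs2 = attrs2,
                 radius_fractions = radius_fractions, predicate = predicate),
            class = c("nf_rule1", "nf_rule"))
}

#' @rdname rules
#' @export
rule_bimolecular <- function(species_a, species_b,
                             kind = c("fuse", "transform", "nest", "unnest"),
                             d_star = NULL, W = 0, d_star_frac = NULL,
                             post = NULL, product = NULL, context = NULL,
                             predicate = NULL) {
  kind <- match.arg(kind)
  if (is.null(d_star) && is.null(d_star_frac))
    stop("give d_star (m) or d_star_frac (fraction of the smaller radius)",
         call. = FALSE)
  if (!is.null(d_star) && d_star <= 0) stop("d_star must be > 0", call. = FALSE)
  if (!is.null(d_star_frac) && (d_star_frac <= 0))
    stop("d_star_frac must be > 0", call. = FALSE)
  if (W < 0) stop("W must be >= 0", call. = FALSE)
  if (kind == "fuse" && is.null(product))
    stop("fuse rules need a product species", call. = FALSE)
  structure(list(order = 2L, kind = kind, species_a = species_a,
                 species_b = species_b, d_star = d_star,
                 d_star_frac = d_star_frac, W = W, post = post,
                 product = product, context = context, predicate = predicate),
            class = c("nf_rule2", "nf_rule"))
}

#' Add a rule or a force field to a model
#'
#' @param model an `nf_model`.
#' @param rule a rule created by one of the [rules] builders.
#' @return the model, invisibly.
#' @export
add_rule <- function(model, rule) {
  stopifnot(inherits(model, "nf_model"), inherits(rule, "nf_rule"))
  for (s in intersect(c("product", "parent_species", "species", "species_a",
                        "species_b"), names(rule)))
    if (!is.null(rule[[s]])) .nf_check_species(model, rule[[s]])
  if (!is.null(rule$context) && !identical(rule$context, "top"))
    .nf_check_species(model, rule$context, "context species")
  slot <- paste0("rules", rule$order)
  model[[slot]] <- c(model[[slot]], list(rule))
  invisible(model)
}

#' Global force fields
#'
#' Force fields act on single particles independently of all other particles
#' (the external-force term of the equation of motion). The evaluator must be
#' pure given the particle view and time, and return finite forces.
#'
#' @param name field name (used in diagnostics).
#' @param fn evaluator `function(state, idx, t)` returning a
#'   `length(idx) x dimension` matrix of forces (N) for the particle rows
#'   `idx`.
#' @param species optional character vector restricting the field to particles
#'   of these species.
#' @param predicate optional `function(state, idx) -> logical` sub-filter
#'   (e.g. on attributes).
#' @return an `nf_field` object; attach with [add_field()].
#' @export
force_field <- function(name, fn, species = NULL, predicate = NULL) {
  stopifnot(is.function(fn))
  structure(list(name = name, fn = fn, species = species,
                 predicate = predicate), class = "nf_field")
}

#' @rdname force_field
#' @param model an `nf_model`.
#' @param field an `nf_field`.
#' @export
add_field <- function(model, field) {
  stopifnot(inherits(model, "nf_model"), inherits(field, "nf_field"))
  model$fields <- c(model$fields, list(field))
  invisible(model)
}

#' A dipole-like force field between two poles
#'
#' Builder for the directed-transport field of the vesicle scenario: particles
#' are pulled toward one of two poles, the sign selected per particle by a
#' `selector` on its attributes (e.g. the coat of a vesicle). The force is
#' constant in magnitude and directed along the line from the particle to its
#' target pole, which reproduces the motor-protein-driven drift the field
#' abstracts.
#'
#' @param name field name.
#' @param pole1,pole2 pole positions (length-`dimension` numeric).
#' @param strength force magnitude (N).
#' @param species species the field applies to.
#' @param selector `function(attrs) -> 1 or 2`, the pole the particle is drawn
#'   toward.
#' @return an `nf_field`.
#' @export
dipole_field <- function(name, pole1, pole2, strength, species, selector) {
  stopifnot(is.function(selector), strength >= 0)
  poles <- list(pole1, pole2)
  fn <- function(state, idx, t) {
    f <- matrix(0, length(idx), state$dim)
    for (k in seq_along(idx)) {
      i <- idx[k]
      tgt <- poles[[selector(state$attrs[[i]])]]
      dvec <- tgt - state$pos[i, ]
      nrm <- sqrt(sum(dvec^2))
      if (nrm > 0) f[k, ] <- strength * dvec / nrm
    }
    f
  }
  force_field(name, fn, species = species)
}
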