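## Property conditioner: molecular descriptors and the tau scaling that maps
## property values onto the [0, 500] condition-label range used as the
## shifted latent prior mean.

ICVAE_PROPERTIES <- c("MW", "logP", "HBA", "HBD", "TPSA", "QED", "SAS")
ICVAE_LATENT_RANGE <- 500

#' Compute molecular descriptors for SMILES strings
#'
#' Computes any subset of the seven descriptors used for conditioning:
#' molecular weight (MW), Crippen logP, Lipinski hydrogen-bond acceptor and
#' donor counts (HBA, HBD), topological polar surface area (TPSA),
#' quantitative estimate of drug-likeness (QED) and the synthetic
#' accessibility score (SAS). Values come from RDKit's standard definitions.
#'
#' @param smiles character vector of SMILES strings.
#' @param names which descriptors to return (default all seven).
#' @return data.frame with columns `smiles`, `canonical`, and one numeric
#'   column per requested descriptor.
#' @examples \dontrun{compute_properties("CCO", c("HBA", "HBD"))}
#' @export
compute_properties <- function(smiles, names = ICVAE_PROPERTIES) {
  stopifnot(all(names %in% ICVAE_PROPERTIES))
  res <- chem_call(smiles, "props")
  if (any(!res$valid))
    stop("invalid SMILES (failed RDKit sanitization): ",
         paste0("'", unique(res$smiles[!res$valid]), "'", collapse = ", "))
  res[, c("smiles", "canonical", names)]
}

#' Construct a property-conditioning specification
#'
#' Fixes a property's value range and the scale factor
#' `tau = 500 / (v_max - v_min)` that maps values onto the condition-label
#' range \[0, 500\]. HBA and HBD are flagged discrete (integer-valued).
#'
#' @param name property name, one of MW, logP, HBA, HBD, TPSA, QED, SAS.
#' @param v_min,v_max property value range, `v_max > v_min`.
#' @return an object of class `icvae_spec` with fields `name`, `v_min`,
#'   `v_max`, `tau`, `discrete`.
#' @examples
#' property_spec("HBA", 0, 10)  # tau = 50
#' @export
property_spec <- function(name, v_min, v_max) {
  name <- match.arg(name, ICVAE_PROPERTIES)
  stopifnot(is.finite(v_min), is.finite(v_max))
  if (v_max <= v_min)
    stop("degenerate property range: v_max must exceed v_min")
  structure(list(name = name, v_min = v_min, v_max = v_max,
                 tau = ICVAE_LATENT_RANGE / (v_max - v_min),
                 discrete = name %in% c("HBA", "HBD")),
            class = "icvae_spec")
}

#' @export
print.icvae_spec <- function(x, ...) {
  cat(sprintf("Property spec %s: range [%g, %g], tau = %g%s\n",
              x$name, x$v_min, x$v_max, x$tau,
              if (x$discrete) " (discrete)" else ""))
  invisible(x)
}

#' Fit conditioning specs from a property table
#'
#' Takes each property's range from the corpus min/max (the default when no
#' range is stated up front).
#'
#' @param props data.frame with one column per property.
#' @param names properties to condition on.
#' @return named list of `icvae_spec`s.
#' @export
fit_property_specs <- function(props, names) {
  specs <- lapply(names, function(nm) {
    v <- props[[nm]]
    if (is.null(v)) stop("property column missing from table: ", nm)
    property_spec(nm, min(v), max(v))
  })
  stats::setNames(specs, names)
}

#' Map property values to scaled condition labels and back
#'
#' `scale_property` computes `tau * (value - v_min)`; in-range values land in
#' \[0, 500\] and out-of-range values are clamped with a warning.
#' `unscale_property` inverts the map; for discrete properties it also
#' reports the nearest integer value.
#'
#' @param value,label finite numeric vectors.
#' @param spec an `icvae_spec`.
#' @return numeric vector of labels (`scale_property`); for
#'   `unscale_property` a numeric vector of values, with attribute
#'   `"rounded"` for discrete specs.
#' @export
scale_property <- function(value, spec) {
  stopifnot(inherits(spec, "icvae_spec"))
  if (!all(is.finite(value))) stop("non-finite property value")
  s <- spec$tau * (value - spec$v_min)
  out <- s < 0 | s > ICVAE_LATENT_RANGE
  if (any(out)) {
    warning(sprintf("%d %s value(s) outside [%g, %g]; clamped",
                    sum(out), spec$name, spec$v_min, spec$v_max))
    s <- pmin(pmax(s, 0), ICVAE_LATENT_RANGE)
  }
  s
}

#' @rdname scale_property
#' @export
unscale_property <- function(label, spec) {
  stopifnot(inherits(spec, "icvae_spec"))
  if (!all(is.finite(label))) stop("non-finite condition label")
  v <- spec$v_min + label / spec$tau
  if (spec$discrete) attr(v, "rounded") <- round(v)
  v
}

## Scaled labels for a property table under a named spec list: one row per
## molecule, one column per conditioned property, values in [0, 500].
condition_labels <- function(props, specs) {
  labs <- vapply(names(specs),
                 function(nm) scale_property(props[[nm]], specs[[nm]]),
                 numeric(nrow(props)))
  matrix(labs, nrow = nrow(props),
         dimnames = list(NULL, names(specs)))
}
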