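# Tissue X-ray attenuation composition model.
#
# The contrast of freeze-dried brain tissue at ~7 keV is modelled from bulk
# composition: a wet-tissue linear attenuation coefficient is computed from a
# mass attenuation coefficient and specific gravity; removing the water
# contribution predicts the dried-tissue coefficient; lipid fractions give the
# phospholipid mass per tissue volume and, through the phosphorus content of
# an average phospholipid, the attenuation contributed by phosphorus alone.

#' Tabulated mass attenuation coefficients for a material
#'
#' A small lookup table of (energy, mass attenuation coefficient) pairs used
#' for linear-in-energy interpolation between tabulated photon energies.
#'
#' @param material material name.
#' @param energies_keV photon energies in keV, strictly increasing.
#' @param mass_attenuation mass attenuation coefficients (cm^2/g), all > 0.
#' @return an object of class `attenuation_table`.
#' @examples
#' water <- attenuation_table("water", c(6, 8), c(24.63, 10.37))
#' interpolate_mass_attenuation(water, 7.13)
#' @export
attenuation_table <- function(material, energies_keV, mass_attenuation) {
  if (length(energies_keV) < 2L)
    stopf("attenuation table for '%s' needs at least 2 entries", material,
          class = "axotomo_domain_error")
  if (any(diff(energies_keV) <= 0))
    stopf("energies must be strictly increasing", class = "axotomo_domain_error")
  if (any(mass_attenuation <= 0))
    stopf("mass attenuation coefficients must be positive",
          class = "axotomo_domain_error")
  structure(list(material = as.character(material),
                 energies_keV = as.numeric(energies_keV),
                 mass_attenuation = as.numeric(mass_attenuation)),
            class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf("<attenuation_table> %s: %d entries, %g-%g keV\n",
              x$material, length(x$energies_keV),
              min(x$energies_keV), max(x$energies_keV)))
  invisible(x)
}

#' Interpolate a mass attenuation coefficient at an energy
#'
#' Linear-in-energy interpolation between the two bracketing tabulated
#' entries.  Interpolation is deliberately linear rather than log-log: linear
#' interpolation of the standard water coefficients at 6 and 8 keV gives
#' 16.6 cm^2/g at 7.13 keV, the value used throughout the composition model,
#' whereas log-log interpolation would give about 14.7 cm^2/g.
#'
#' @param table an [attenuation_table()].
#' @param energy_keV query energy in keV; must lie within the tabulated
#'   range (no extrapolation).
#' @return mass attenuation coefficient in cm^2/g.
#' @export
interpolate_mass_attenuation <- function(table, energy_keV) {
  stopifnot(inherits(table, "attenuation_table"))
  e <- table$energies_keV
  if (energy_keV < min(e) || energy_keV > max(e))
    stopf("energy %.4g keV outside tabulated range [%g, %g] for '%s'",
          energy_keV, min(e), max(e), table$material,
          class = "axotomo_range_error")
  stats::approx(e, table$mass_attenuation, xout = energy_keV,
                method = "linear", ties = "ordered")$y
}

#' Bulk composition of a tissue
#'
#' @param name tissue name.
#' @param water_mass_fraction mass fraction of water, in \[0, 1\].
#' @param specific_gravity tissue density in g/cm^3.
#' @param lipid_fraction_of_dry lipid mass fraction of the dry residue.
#' @param phospholipid_fraction_of_lipid phospholipid mass fraction of the
#'   lipid.
#' @return an object of class `tissue_composition`.
#' @examples
#' myelin <- tissue_composition("myelin", 0.40, 1.03, 0.71, 0.44)
#' phospholipid_density(myelin)
#' @export
tissue_composition <- function(name, water_mass_fraction, specific_gravity,
                               lipid_fraction_of_dry = 0,
                               phospholipid_fraction_of_lipid = 0) {
  fr <- c(water_mass_fraction, lipid_fraction_of_dry,
          phospholipid_fraction_of_lipid)
  if (any(fr < 0 | fr > 1))
    stopf("fractions must lie in [0, 1]", class = "axotomo_domain_error")
  if (specific_gravity <= 0)
    stopf("specific gravity must be positive", class = "axotomo_domain_error")
  structure(list(name = as.character(name),
                 water_mass_fraction = water_mass_fraction,
                 specific_gravity = specific_gravity,
                 lipid_fraction_of_dry = lipid_fraction_of_dry,
                 phospholipid_fraction_of_lipid = phospholipid_fraction_of_lipid),
            class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat(sprintf(paste0("<tissue_composition> %s: water %.0f%%, rho %.2f g/cm^3, ",
                     "lipid %.0f%% of dry, phospholipid %.0f%% of lipid\n"),
              x$name, 100 * x$water_mass_fraction, x$specific_gravity,
              100 * x$lipid_fraction_of_dry,
              100 * x$phospholipid_fraction_of_lipid))
  invisible(x)
}

#' Element constants for attenuation bookkeeping
#'
#' @param symbol element symbol.
#' @param atomic_mass atomic mass in g/mol.
#' @param mass_attenuation mass attenuation coefficient at the working
#'   energy, cm^2/g.
#' @return an object of class `element_spec`.
#' @export
element_spec <- function(symbol, atomic_mass, mass_attenuation) {
  if (atomic_mass <= 0 || mass_attenuation <= 0)
    stopf("element constants must be positive", class = "axotomo_domain_error")
  structure(list(symbol = symbol, atomic_mass = atomic_mass,
                 mass_attenuation = mass_attenuation),
            class = "element_spec")
}

#' Average phospholipid molecule
#'
#' Defaults describe an average C18 phospholipid: 750 Da with one phosphorus
#' atom per molecule.
#'
#' @param mean_molecular_weight mean molecular weight in Da.
#' @param phosphorus_atoms_per_molecule phosphorus atoms per molecule.
#' @return an object of class `phospholipid_spec`.
#' @export
phospholipid_spec <- function(mean_molecular_weight = 750,
                              phosphorus_atoms_per_molecule = 1L) {
  if (mean_molecular_weight <= 0 || phosphorus_atoms_per_molecule < 1)
    stopf("invalid phospholipid constants", class = "axotomo_domain_error")
  structure(list(mean_molecular_weight = mean_molecular_weight,
                 phosphorus_atoms_per_molecule = phosphorus_atoms_per_molecule),
            class = "phospholipid_spec")
}

#' Linear attenuation coefficient from mass attenuation and density
#'
#' @param mass_attenuation mass attenuation coefficient, cm^2/g (> 0).
#' @param density material density, g/cm^3 (> 0).
#' @return linear attenuation coefficient in cm^-1.
#' @examples
#' linear_attenuation(16.7, 1.03)  # wet brain tissue at 7.13 keV, ~17.2
#' @export
linear_attenuation <- function(mass_attenuation, density) {
  if (any(mass_attenuation <= 0) || any(density <= 0))
    stopf("mass attenuation and density must be positive",
          class = "axotomo_domain_error")
  mass_attenuation * density
}

#' Predicted linear attenuation after water removal
#'
#' Freeze drying removes the water from the tissue; the remaining dry matter
#' attenuates by `mu_wet` minus the water contribution.  The default
#' convention takes the water partial density as `w` grams per cm^3 of tissue
#' (i.e. multiplies the water mass fraction by 1.00 g/cm^3); setting
#' `density_weighted = TRUE` instead uses `w * specific_gravity`, which
#' attributes the water mass to the tissue's own density.  The default is the
#' convention consistent with the printed whole-brain (3.9 cm^-1) and myelin
#' (10.6 cm^-1) predictions; the density-weighted variant gives about 3.5 and
#' 10.4 cm^-1.
#'
#' @param mu_wet wet-tissue linear attenuation coefficient, cm^-1.
#' @param comp a [tissue_composition()] (only the water fraction, and under
#'   the density-weighted variant the specific gravity, are used).
#' @param mu_rho_water mass attenuation coefficient of water at the working
#'   energy, cm^2/g (16.6 at 7.13 keV).
#' @param density_weighted use `w * specific_gravity` as the water partial
#'   density instead of `w * 1.00`.
#' @return dried-tissue linear attenuation coefficient in cm^-1.
#' @examples
#' brain <- tissue_composition("whole brain", 0.80, 1.03, 0.37, 0.58)
#' dried_attenuation(17.2, brain, 16.6)  # ~3.9
#' @export
dried_attenuation <- function(mu_wet, comp, mu_rho_water,
                              density_weighted = FALSE) {
  stopifnot(inherits(comp, "tissue_composition"))
  if (mu_wet <= 0)
    stopf("mu_wet must be positive", class = "axotomo_domain_error")
  water_density <- if (density_weighted)
    comp$water_mass_fraction * comp$specific_gravity
  else comp$water_mass_fraction * 1.00
  mu <- mu_wet - water_density * mu_rho_water
  if (mu < 0)
    stopf(paste0("water removal for '%s' yields a negative coefficient ",
                 "(%.3g cm^-1): composition inconsistent with mu_wet"),
          comp$name, mu, class = "axotomo_composition_error")
  mu
}

#' Phospholipid mass per unit tissue volume
#'
#' `(1 - w) * rho * lipid_fraction_of_dry * phospholipid_fraction_of_lipid`,
#' the mass of phospholipid contained in one cm^3 of wet tissue.
#'
#' @param comp a [tissue_composition()].
#' @return phospholipid density in g/cm^3.
#' @export
phospholipid_density <- function(comp) {
  stopifnot(inherits(comp, "tissue_composition"))
  (1 - comp$water_mass_fraction) * comp$specific_gravity *
    comp$lipid_fraction_of_dry * comp$phospholipid_fraction_of_lipid
}

#' Linear attenuation contributed by phosphorus atoms
#'
#' The phosphorus partial density is the phospholipid density times the mass
#' fraction of phosphorus in the average phospholipid molecule; multiplying
#' by the elemental mass attenuation coefficient gives the linear attenuation
#' due to phosphorus alone.
#'
#' @param pl_density phospholipid mass per tissue volume, g/cm^3 (>= 0).
#' @param pl a [phospholipid_spec()].
#' @param p an [element_spec()] for phosphorus; see [default_phosphorus()].
#' @return linear attenuation coefficient in cm^-1.
#' @examples
#' phosphorus_attenuation(0.193, phospholipid_spec(), default_phosphorus())
#' @export
phosphorus_attenuation <- function(pl_density, pl = phospholipid_spec(),
                                   p = default_phosphorus()) {
  stopifnot(inherits(pl, "phospholipid_spec"), inherits(p, "element_spec"))
  if (pl_density < 0)
    stopf("phospholipid density must be non-negative",
          class = "axotomo_domain_error")
  pl_density *
    (pl$phosphorus_atoms_per_molecule * p$atomic_mass / pl$mean_molecular_weight) *
    p$mass_attenuation
}

#' Phosphorus constants at 7.13 keV
#'
#' Atomic mass 30.97 g/mol; mass attenuation coefficient 109.0 cm^2/g at
#' 7.13 keV.
#'
#' @return an [element_spec()].
#' @export
default_phosphorus <- function() element_spec("P", 30.97, 109.0)

# ---- material / tissue database --------------------------------------------

#' Built-in material attenuation database
#'
#' Reads the plain-text material table shipped with the package (or a
#' user-supplied file in the same format): tab-separated columns `material`,
#' `energy_keV`, `value`, `kind`, where `kind` is `mass_cm2_g` for mass
#' attenuation coefficients or `linear_cm_1` for directly stated linear
#' coefficients (e.g. cured epoxy resin, 9.0 cm^-1 at 7.13 keV).
#'
#' @param path optional path to an alternative database file.
#' @return a tibble with one row per (material, energy) entry.
#' @export
default_materials <- function(path = NULL) {
  path <- path %||% system.file("extdata", "materials.tsv", package = "axotomo")
  d <- read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(d)
}

#' Built-in tissue composition database
#'
#' Tab-separated columns: `tissue`, `water_mass_fraction`, `specific_gravity`,
#' `lipid_fraction_of_dry`, `phospholipid_fraction_of_lipid`,
#' `mass_attenuation_cm2_g` (bulk tissue mass attenuation coefficient at
#' 7.13 keV).
#'
#' @param path optional path to an alternative database file.
#' @return a tibble with one row per tissue.
#' @export
default_tissues <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tissues.tsv", package = "axotomo")
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}

#' Material attenuation table from the database
#'
#' @param material material name present in the database.
#' @param db database tibble from [default_materials()].
#' @return an [attenuation_table()].
#' @export
material_table <- function(material, db = default_materials()) {
  rows <- db[db$material == material & db$kind == "mass_cm2_g", ]
  if (nrow(rows) == 0)
    stopf("no mass attenuation entries for material '%s'", material,
          class = "axotomo_domain_error")
  rows <- rows[order(rows$energy_keV), ]
  if (nrow(rows) == 1L)  # single-energy entries are stated constants
    return(structure(list(material = material,
                          energies_keV = rows$energy_keV,
                          mass_attenuation = rows$value),
                     class = "attenuation_table"))
  attenuation_table(material, rows$energy_keV, rows$value)
}

# mass attenuation at an energy, accepting single-entry stated constants
mass_attenuation_at <- function(table, energy_keV) {
  if (length(table$energies_keV) == 1L) {
    if (abs(table$energies_keV - energy_keV) > 1e-9)
      stopf("material '%s' has a stated coefficient only at %g keV",
            table$material, table$energies_keV, class = "axotomo_range_error")
    return(table$mass_attenuation)
  }
  interpolate_mass_attenuation(table, energy_keV)
}

#' Composition derivation report for a tissue
#'
#' Runs the full composition chain for one tissue at one energy: wet linear
#' attenuation, dried (water-removed) attenuation, phospholipid density and
#' the phosphorus contribution.  Values are reported both at full precision
#' and rounded half-up to the precision conventionally printed for each
#' quantity (one decimal for cm^-1, three for g/cm^3 phospholipid densities,
#' two for the phosphorus contributions).
#'
#' @param tissue tissue name in the tissue database.
#' @param energy_keV working energy (default 7.13 keV).
#' @param tissues,materials database tibbles.
#' @param pl,p phospholipid and phosphorus constants.
#' @return a tibble with columns `quantity`, `value`, `printed`, `units`.
#' @examples
#' composition_report("myelin")
#' @export
composition_report <- function(tissue, energy_keV = 7.13,
                               tissues = default_tissues(),
                               materials = default_materials(),
                               pl = phospholipid_spec(),
                               p = default_phosphorus()) {
  row <- tissues[tissues$tissue == tissue, ]
  if (nrow(row) != 1L)
    stopf("tissue '%s' not found in database", tissue,
          class = "axotomo_domain_error")
  comp <- tissue_composition(tissue, row$water_mass_fraction,
                             row$specific_gravity, row$lipid_fraction_of_dry,
                             row$phospholipid_fraction_of_lipid)
  mu_rho_tissue <- row$mass_attenuation_cm2_g
  mu_rho_water <- mass_attenuation_at(material_table("water", materials),
                                      energy_keV)
  mu_wet <- linear_attenuation(mu_rho_tissue, comp$specific_gravity)
  mu_dry <- dried_attenuation(mu_wet, comp, mu_rho_water)
  pld <- phospholipid_density(comp)
  mu_p <- phosphorus_attenuation(pld, pl, p)
  tibble::tibble(
    quantity = c("mass_attenuation_tissue", "mass_attenuation_water",
                 "linear_attenuation_wet", "linear_attenuation_dried",
                 "phospholipid_density", "phosphorus_attenuation"),
    value = c(mu_rho_tissue, mu_rho_water, mu_wet, mu_dry, pld, mu_p),
    printed = c(round_half_up(mu_rho_tissue, 1), round_half_up(mu_rho_water, 1),
                round_half_up(mu_wet, 1), round_half_up(mu_dry, 1),
                round_half_up(pld, 3), round_half_up(mu_p, 2)),
    units = c("cm^2/g", "cm^2/g", "cm^-1", "cm^-1", "g/cm^3", "cm^-1"))
}
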