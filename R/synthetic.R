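#' Synthetic background life table
#'
#' Gompertz--Makeham annual death probabilities with an added
#' infant-mortality term at age 0:
#' `q(age) = 1 - exp(-(a + b * exp(c * age)))`, clamped to \[0, 1\], with
#' probability 1 at the closing age.  Defaults emulate a low-mortality
#' population (infant mortality ~0.2%, life expectancy in the low 80s)
#' whose discounted life expectancy at a 2% annual rate is about 40 years.
#'
#' @param makeham_a Age-independent hazard component (per year).
#' @param gompertz_b Senescent hazard scale (per year).
#' @param gompertz_c Senescent hazard log-slope (per year of age).
#' @param infant_excess Extra hazard applied at age 0 only (per year).
#' @param closing_age Final table age; death is certain there.
#' @return Tibble `age_years` (0..closing_age), `p_death_annual`.
#' @export
make_lifetable <- function(makeham_a = 2e-4, gompertz_b = 7e-6,
                           gompertz_c = 0.112, infant_excess = 0.0016,
                           closing_age = 110) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c >= 0,
            infant_excess >= 0, closing_age >= 1)
  age <- 0:closing_age
  hazard <- makeham_a + gompertz_b * exp(gompertz_c * age)
  hazard[1] <- hazard[1] + infant_excess
  p <- pmin(pmax(1 - exp(-hazard), 0), 1)
  p[length(p)] <- 1
  tibble::tibble(age_years = age, p_death_annual = p)
}

#' Synthetic digitized survival curves for the clinically identified arm
#'
#' Stand-ins for digitized Kaplan--Meier overall-survival (OS) and
#' ventilation-free-survival (VFS) curves of clinically identified,
#' enzyme-replacement-treated infantile-onset patients: an exponential
#' early decline that reaches a plateau no later than `plateau_month`, flat
#' thereafter, at monthly resolution.  VFS counts ventilation-or-death as
#' the event, so it must lie at or below OS; with a shared early hazard and
#' a lower plateau that ordering holds pointwise.  Plateau levels are free
#' shape parameters, not published values.
#'
#' @param early_hazard Event hazard per month during the decline phase.
#' @param plateau_level_os,plateau_level_vfs Plateau survival levels, with
#'   `0 <= plateau_level_vfs <= plateau_level_os <= 1`.
#' @param plateau_month Month by which both curves must have plateaued.
#' @param end_month Last tabulated month (>= 150 covers the follow-up the
#'   splicing rules assume).
#' @return List of two `km_curve` tibbles: `os` and `vfs`, each with
#'   columns `time_months`, `survival`.
#' @export
make_km_curves <- function(early_hazard = 0.02, plateau_level_os = 0.70,
                           plateau_level_vfs = 0.45, plateau_month = 48,
                           end_month = 150) {
  if (!(plateau_level_vfs <= plateau_level_os && plateau_level_os <= 1 &&
        plateau_level_vfs >= 0)) {
    stop("need 0 <= plateau_level_vfs <= plateau_level_os <= 1", call. = FALSE)
  }
  stopifnot(early_hazard >= 0, plateau_month > 0, end_month >= plateau_month)
  if (plateau_level_os < 1 &&
      exp(-early_hazard * plateau_month) > plateau_level_os + 1e-12) {
    stop("early_hazard too small to reach the OS plateau by plateau_month",
         call. = FALSE)
  }
  shape <- function(level) {
    t <- 0:end_month
    s <- pmax(exp(-early_hazard * t), level)
    km_curve(tibble::tibble(time_months = t, survival = s))
  }
  list(os = shape(plateau_level_os), vfs = shape(plateau_level_vfs))
}

#' Synthetic quality-of-life population norms by age
#'
#' Utility norms anchored at `reference` in the 16--19-year band, constant
#' below it, declining linearly per decade band above it (20--29 one step,
#' 30--39 two, ...), with ages 90+ clamped to the 80--89 band value.
#'
#' @param reference Norm value in the 16--19-year reference band.
#' @param decline_per_decade Absolute utility drop per decade band.
#' @param max_age Last tabulated age.
#' @return Tibble `age_years`, `norm`.
#' @export
make_qol_norms <- function(reference = 0.95, decline_per_decade = 0.02,
                           max_age = 110) {
  stopifnot(reference > 0, reference <= 1, decline_per_decade >= 0)
  age <- 0:max_age
  # decade bands above the 16-19 reference: 20-29 = 1 step ... 80-89 = 7; 90+ clamps to 7
  norm <- pmax(reference - decline_per_decade * pmax(0, pmin(floor(age / 10) - 1, 7)), 0)
  norm[age < 20] <- reference
  tibble::tibble(age_years = age, norm = norm)
}

#' Synthetic weight-for-age growth curve
#'
#' Monotone growth from birth weight to adult weight by `saturation_age`,
#' constant after, following a concave power curve (fast infant growth,
#' slowing through childhood) as a stand-in for national standard body
#' weight tables.
#'
#' @param birth_kg Weight at age 0.
#' @param adult_kg Asymptotic adult weight, reached at `saturation_age`.
#' @param saturation_age Age (years) at which adult weight is reached.
#' @param growth_exponent Concavity of the growth curve in (0, 1\].
#' @param max_age Last tabulated age.
#' @return Tibble `age_years`, `weight_kg`.
#' @export
make_weight_table <- function(birth_kg = 3, adult_kg = 60, saturation_age = 18,
                              growth_exponent = 0.8, max_age = 110) {
  stopifnot(birth_kg > 0, adult_kg > birth_kg, saturation_age > 0,
            growth_exponent > 0, growth_exponent <= 1)
  age <- 0:max_age
  frac <- pmin(age / saturation_age, 1)^growth_exponent
  tibble::tibble(age_years = age, weight_kg = birth_kg + (adult_kg - birth_kg) * frac)
}

#' Generate the full synthetic input bundle
#'
#' Builds every external input the pipeline needs -- background life table,
#' digitized-style survival curves for the clinical arm, quality-of-life
#' norms and weight-for-age -- from deterministic closed-form shapes.  With
#' `noise = 0` the bundle is a pure function of its parameters; a positive
#' `noise` adds seeded multiplicative jitter to the survival curves (then
#' repairs them to valid monotone curves), exercising the digitization
#'-noise repair path.
#'
#' @param seed Integer seed (only used when `noise > 0`).
#' @param noise Standard deviation of log-scale jitter on the curves.
#' @param lifetable_args,km_args,qol_args,weight_args Named lists of
#'   overrides passed to the respective generators.
#' @return A `synthetic_bundle`: list with `life_table`, `km_os`, `km_vfs`,
#'   `qol_norms`, `weight`, and a `manifest` recording generation
#'   parameters and seed.
#' @export
synthetic_bundle <- function(seed = 1L, noise = 0,
                             lifetable_args = list(), km_args = list(),
                             qol_args = list(), weight_args = list()) {
  life_table <- do.call(make_lifetable, lifetable_args)
  curves <- do.call(make_km_curves, km_args)
  qol <- do.call(make_qol_norms, qol_args)
  weight <- do.call(make_weight_table, weight_args)
  if (noise > 0) {
    curves <- withr::with_seed(as.integer(seed), {
      jitter_curve <- function(curve) {
        s <- curve$survival * exp(stats::rnorm(nrow(curve), 0, noise))
        s[1] <- 1
        repair_km_curve(tibble::tibble(time_months = curve$time_months,
                                       survival = pmin(pmax(s, 0), 1)))
      }
      list(os = jitter_curve(curves$os), vfs = jitter_curve(curves$vfs))
    })
    # jitter can break the VFS <= OS ordering; restore it
    curves$vfs$survival <- pmin(curves$vfs$survival, curves$os$survival)
  }
  structure(list(
    life_table = life_table,
    km_os = curves$os,
    km_vfs = curves$vfs,
    qol_norms = qol,
    weight = weight,
    manifest = list(
      seed = as.integer(seed), noise = noise,
      lifetable_args = lifetable_args, km_args = km_args,
      qol_args = qol_args, weight_args = weight_args
    )
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat(sprintf("  life table: ages 0-%d\n", max(x$life_table$age_years)))
  cat(sprintf("  KM curves: OS plateau %.3f, VFS plateau %.3f (months 0-%d)\n",
              min(x$km_os$survival), min(x$km_vfs$survival),
              max(x$km_os$time_months)))
  cat(sprintf("  seed %d, noise %g\n", x$manifest$seed, x$manifest$noise))
  invisible(x)
}

#' Write a synthetic bundle to CSV files
#'
#' Emits the same plain-text formats the pipeline consumes (`life_table.csv`,
#' `km_os.csv`, `km_vfs.csv`, `qol_norms.csv`, `weight.csv`) plus a
#' `manifest.json` recording the generation parameters and seed.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    life_table = file.path(dir, "life_table.csv"),
    km_os = file.path(dir, "km_os.csv"),
    km_vfs = file.path(dir, "km_vfs.csv"),
    qol_norms = file.path(dir, "qol_norms.csv"),
    weight = file.path(dir, "weight.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(bundle$life_table, paths["life_table"], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$km_os), paths["km_os"], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$km_vfs), paths["km_vfs"], row.names = FALSE)
  utils::write.csv(bundle$qol_norms, paths["qol_norms"], row.names = FALSE)
  utils::write.csv(bundle$weight, paths["weight"], row.names = FALSE)
  jsonlite::write_json(bundle$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read an input bundle from CSV files
#'
#' Counterpart of [write_bundle()]; also accepts user-supplied real data in
#' the same layout (e.g. digitized survival coordinates and a national life
#' table), validating each component.
#'
#' @param dir Directory containing the bundle CSVs.
#' @return A `synthetic_bundle`-classed list (manifest read if present).
#' @export
read_bundle <- function(dir) {
  need <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    tibble::as_tibble(utils::read.csv(path))
  }
  life_table <- need("life_table")
  stopifnot(all(c("age_years", "p_death_annual") %in% names(life_table)))
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  structure(list(
    life_table = life_table,
    km_os = km_curve(need("km_os")),
    km_vfs = km_curve(need("km_vfs")),
    qol_norms = need("qol_norms"),
    weight = need("weight"),
    manifest = manifest
  ), class = "synthetic_bundle")
}
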