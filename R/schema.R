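#' Canonical exposure types
#'
#' The nine contaminant classes scored from the occupational survey, as
#' short machine ids with display labels.
#'
#' @return Named character vector: names are type ids, values are labels.
#' @export
exposure_types <- function() {
  c(pm              = "Particulate Matter (PM)",
    voc             = "Volatile Organic Compounds (VOCs)",
    pesticides      = "Pesticides",
    metals          = "Metals",
    biologicals     = "Biological Exposures",
    combustion      = "Combustion and Diesel Exhaust",
    electromagnetic = "Electromagnetic Exposure",
    radiation       = "Radiation",
    corrosives      = "Corrosives")
}

#' Recognised metal subcomponents
#' @return Character vector of subcomponent ids.
#' @export
metal_subcomponent_levels <- function() {
  c("lead", "mercury", "cadmium", "arsenic", "iron", "welding", "other_metal")
}

yn <- c(yes = 1, no = 0)

new_item <- function(question_id, map = yn, subcomponent = NULL) {
  stopifnot(is.character(question_id), length(question_id) == 1L,
            is.numeric(map), !is.null(names(map)),
            all(map >= 0), all(map <= 1))
  list(question_id = question_id, map = map, subcomponent = subcomponent)
}

new_factor <- function(factor_id, weight, items) {
  stopifnot(is.numeric(weight), weight > 0, length(items) >= 1L)
  list(factor_id = factor_id, weight = weight, items = items)
}

#' Default illustrative exposure schema
#'
#' A complete schema over the nine exposure types. Structure mirrors the
#' survey design: each type holds one or more exposure factors, each factor
#' a set of question items with response-to-contribution maps in \[0, 1\].
#' The PM type carries the documented two-factor / 18-item structure
#' (general exposure likelihood plus specific sources); every other type
#' ships two smaller factors. All weights are equal. The item lists and
#' weights are illustrative defaults: real deployments supply their own
#' schema file via [read_schema()] reflecting expert assessment of factor
#' contributions.
#'
#' @return An object of class `occx_schema`.
#' @export
default_schema <- function() {
  ord3 <- c(never = 0, sometimes = 0.5, often = 1)
  pm_general <- new_factor("pm_general", 1, list(
    new_item("pm_dusty_env"), new_item("pm_visible_dust"),
    new_item("pm_dust_freq", ord3), new_item("pm_respirator"),
    new_item("pm_sanding"), new_item("pm_sweeping"),
    new_item("pm_demolition"), new_item("pm_outdoor_dust")))
  pm_sources <- new_factor("pm_sources", 1, list(
    new_item("pm_src_silica"), new_item("pm_src_talc"),
    new_item("pm_src_fibers"), new_item("pm_src_wood"),
    new_item("pm_src_grain"), new_item("pm_src_cement"),
    new_item("pm_src_coal"), new_item("pm_src_asbestos"),
    new_item("pm_src_powder"), new_item("pm_src_weld_fume")))
  voc <- list(
    new_factor("voc_solvents", 1, list(
      new_item("voc_solvent_use"), new_item("voc_degreasing"),
      new_item("voc_paint"), new_item("voc_glue"),
      new_item("voc_freq", ord3))),
    new_factor("voc_fuels", 1, list(
      new_item("voc_gasoline"), new_item("voc_printing"),
      new_item("voc_drycleaning"))))
  pest <- list(
    new_factor("pest_application", 1, list(
      new_item("pest_apply"), new_item("pest_mix"),
      new_item("pest_freq", ord3))),
    new_factor("pest_ambient", 1, list(
      new_item("pest_field_work"), new_item("pest_greenhouse"),
      new_item("pest_fumigation"))))
  metals <- list(
    new_factor("metal_specific", 1, list(
      new_item("met_lead",     subcomponent = "lead"),
      new_item("met_mercury",  subcomponent = "mercury"),
      new_item("met_cadmium",  subcomponent = "cadmium"),
      new_item("met_arsenic",  subcomponent = "arsenic"),
      new_item("met_iron",     subcomponent = "iron"),
      new_item("met_welding",  subcomponent = "welding"),
      new_item("met_other",    subcomponent = "other_metal"))),
    new_factor("metal_activities", 1, list(
      new_item("met_grinding"), new_item("met_plating"),
      new_item("met_soldering"), new_item("met_casting"))))
  bio <- list(
    new_factor("bio_animal", 1, list(
      new_item("bio_animals"), new_item("bio_animal_products"))),
    new_factor("bio_organic", 1, list(
      new_item("bio_mold"), new_item("bio_sewage"),
      new_item("bio_lab_agents"))))
  comb <- list(
    new_factor("comb_diesel", 1, list(
      new_item("comb_diesel_exhaust"), new_item("comb_truck_bay"),
      new_item("comb_freq", ord3))),
    new_factor("comb_other", 1, list(
      new_item("comb_fire_smoke"), new_item("comb_furnace"))))
  em <- list(
    new_factor("em_fields", 1, list(
      new_item("em_powerlines"), new_item("em_transformers"),
      new_item("em_induction"))),
    new_factor("em_equipment", 1, list(
      new_item("em_radar"), new_item("em_rf_equipment"))))
  rad <- list(
    new_factor("rad_ionizing", 1, list(
      new_item("rad_xray"), new_item("rad_isotopes"),
      new_item("rad_nuclear"))),
    new_factor("rad_monitoring", 1, list(
      new_item("rad_badge"), new_item("rad_uv"))))
  corr <- list(
    new_factor("corr_acids", 1, list(
      new_item("corr_acid"), new_item("corr_caustic"),
      new_item("corr_freq", ord3))),
    new_factor("corr_cleaning", 1, list(
      new_item("corr_industrial_clean"), new_item("corr_etching"))))

  types <- list(
    list(type = "pm", factors = list(pm_general, pm_sources)),
    list(type = "voc", factors = voc),
    list(type = "pesticides", factors = pest),
    list(type = "metals", factors = metals),
    list(type = "biologicals", factors = bio),
    list(type = "combustion", factors = comb),
    list(type = "electromagnetic", factors = em),
    list(type = "radiation", factors = rad),
    list(type = "corrosives", factors = corr))
  labels <- exposure_types()
  for (i in seq_along(types)) types[[i]]$label <- unname(labels[types[[i]]$type])
  structure(types, class = "occx_schema")
}

#' Construct a schema from a plain list
#'
#' Validates the nested type/factor/item structure and returns a classed
#' schema. Every question item must belong to exactly one factor of one
#' type, factor weights must be positive, and contribution maps must lie in
#' \[0, 1\].
#'
#' @param x List of type entries (see [default_schema()] for the shape).
#' @return An `occx_schema`.
#' @export
as_schema <- function(x) {
  if (inherits(x, "occx_schema")) return(x)
  stopifnot(is.list(x), length(x) >= 1L)
  s <- structure(x, class = "occx_schema")
  validate_schema(s)
  s
}

#' Validate schema invariants
#' @param schema An `occx_schema`.
#' @return The schema, invisibly; errors on violation.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "occx_schema"))
  seen <- character(0)
  for (ty in schema) {
    if (is.null(ty$type) || !nzchar(ty$type)) stop("schema type missing an id")
    if (length(ty$factors) < 1L)
      stop("exposure type '", ty$type, "' has no factors")
    for (f in ty$factors) {
      if (!is.numeric(f$weight) || f$weight <= 0)
        stop("factor '", f$factor_id, "' has non-positive weight")
      if (length(f$items) < 1L)
        stop("factor '", f$factor_id, "' has no items")
      for (it in f$items) {
        if (it$question_id %in% seen)
          stop("question '", it$question_id,
               "' appears in more than one factor")
        seen <- c(seen, it$question_id)
        if (any(it$map < 0) || any(it$map > 1))
          stop("contribution map of '", it$question_id, "' outside [0, 1]")
        if (max(it$map) <= 0)
          stop("item '", it$question_id, "' has no attainable contribution")
      }
    }
  }
  invisible(schema)
}

#' Flatten a schema to an item table
#'
#' @param schema An `occx_schema`.
#' @return data.frame with one row per question item: `question_id`, `type`,
#'   `factor_id`, `weight`, `max_contrib`, `subcomponent`.
#' @export
schema_items <- function(schema) {
  stopifnot(inherits(schema, "occx_schema"))
  rows <- list()
  for (ty in schema) for (f in ty$factors) for (it in f$items) {
    rows[[length(rows) + 1L]] <- data.frame(
      question_id = it$question_id, type = ty$type,
      factor_id = f$factor_id, weight = f$weight,
      max_contrib = max(it$map),
      subcomponent = if (is.null(it$subcomponent)) NA_character_
                     else it$subcomponent,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# lookup table question/response -> contribution, used by the vectorized scorer
schema_contrib_table <- function(schema) {
  rows <- list()
  for (ty in schema) for (f in ty$factors) for (it in f$items) {
    rows[[length(rows) + 1L]] <- data.frame(
      question_id = it$question_id, response = names(it$map),
      contrib = unname(it$map), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read a schema from a YAML file
#'
#' The file holds a list of exposure types; each type has `type`, optional
#' `label`, and `factors`, each factor `factor_id`, `weight` and `items`,
#' each item `question_id`, a `map` of response level to contribution, and
#' an optional `subcomponent` tag (metal items).
#'
#' @param path Path to the YAML file.
#' @return An `occx_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  types <- lapply(raw, function(ty) {
    ty$factors <- lapply(ty$factors, function(f) {
      f$items <- lapply(f$items, function(it) {
        new_item(it$question_id, unlist(it$map), it$subcomponent)
      })
      new_factor(f$factor_id, f$weight, f$items)
    })
    ty
  })
  as_schema(types)
}

#' Write a schema to a YAML file
#' @param schema An `occx_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "occx_schema"))
  out <- lapply(unclass(schema), function(ty) {
    ty$factors <- lapply(ty$factors, function(f) {
      f$items <- lapply(f$items, function(it) {
        x <- list(question_id = it$question_id, map = as.list(it$map))
        if (!is.null(it$subcomponent)) x$subcomponent <- it$subcomponent
        x
      })
      f
    })
    ty
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.occx_schema <- function(x, ...) {
  it <- schema_items(x)
  cat("<occx_schema> ", length(x), " exposure types, ",
      length(unique(it$factor_id)), " factors, ", nrow(it), " items\n",
      sep = "")
  for (ty in x) {
    n_it <- sum(it$type == ty$type)
    cat("  ", format(ty$type, width = 16), length(ty$factors),
        " factor(s), ", n_it, " item(s)\n", sep = "")
  }
  invisible(x)
}
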