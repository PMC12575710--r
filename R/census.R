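# Conservation census of KZFP units across species, tiered by how widely a
# unit (a distinct zinc-finger-array identifier) is shared.

CENSUS_TIERS <- c("species-unique", "clade-shared", "mammal-shared", "beyond-mammal")

#' Tier KZFP units by cross-species conservation
#'
#' Assigns each unit, per species, to the widest tier its sharing pattern
#' supports: shared with any non-mammal species (`beyond-mammal`); else
#' shared with a mammal outside the species' own clade (`mammal-shared`);
#' else shared with another species of the same clade (`clade-shared`); else
#' `species-unique`. Counts include multiplicity — each copy of a unit in a
#' species counts.
#'
#' @param units Tibble with columns `species` and `unit_id`; an optional `n`
#'   column gives per-species multiplicity (default: one row = one copy).
#' @param clades Tibble with columns `species`, `clade` and `mammal`
#'   (logical); must cover every species in `units`.
#' @return A tibble `species`, `tier` (factor over the four tiers), `n`
#'   (unit count including multiplicity), complete over all species x tiers.
#' @export
conservation_census <- function(units, clades) {
  stopifnot(all(c("species", "unit_id") %in% names(units)),
            all(c("species", "clade", "mammal") %in% names(clades)))
  missing_sp <- setdiff(unique(units$species), clades$species)
  if (length(missing_sp) > 0L) {
    abort(paste("species absent from clade map:", paste(missing_sp, collapse = ", ")))
  }
  u <- units
  if (!"n" %in% names(u)) u$n <- 1L
  u <- u %>%
    group_by(.data$species, .data$unit_id) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    left_join(clades, by = "species")

  presence <- u %>% distinct(.data$unit_id, .data$species, .data$clade, .data$mammal)

  tier_of <- function(unit, sp, cl) {
    others <- presence[presence$unit_id == unit & presence$species != sp, ]
    if (any(!others$mammal)) return("beyond-mammal")
    if (any(others$mammal & others$clade != cl)) return("mammal-shared")
    if (any(others$clade == cl)) return("clade-shared")
    "species-unique"
  }
  u$tier <- mapply(tier_of, u$unit_id, u$species, u$clade)

  u %>%
    mutate(tier = factor(.data$tier, levels = CENSUS_TIERS)) %>%
    group_by(.data$species, .data$tier, .drop = FALSE) %>%
    summarise(n = sum(.data$n), .groups = "drop")
}
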