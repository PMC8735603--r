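#' Stack binary species maps into a richness surface
#'
#' Cellwise sum of per-species presence/absence maps. With
#' `na_as_absence = TRUE` (the default), a nodata cell in an individual
#' species map contributes 0 — missing predictions are classified as
#' absences before richness computation; with `FALSE`, nodata propagates to
#' the richness surface.
#'
#' @param binary_maps named list of aligned binary layers (values 0/1,
#'   `NA` = nodata), one per species.
#' @param na_as_absence treat per-species nodata as absence (default
#'   `TRUE`).
#' @param guild label recorded on the result (default `"all"`).
#' @return A `richness_map`: a [grid_layer()] of counts with attributes
#'   `species` (contributing species names) and `guild`.
#' @export
stack_richness <- function(binary_maps, na_as_absence = TRUE, guild = "all") {
  if (length(binary_maps) == 0)
    stop("`binary_maps` is empty", call. = FALSE)
  dims <- vapply(binary_maps, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("binary maps do not share one grid", call. = FALSE)
  mats <- lapply(binary_maps, unclass)
  if (na_as_absence) {
    total <- Reduce(`+`, lapply(mats, function(m) {
      m[is.na(m)] <- 0; m
    }))
  } else {
    total <- Reduce(`+`, mats)
  }
  out <- as_result_layer(total, binary_maps[[1]])
  attr(out, "species") <- names(binary_maps) %||%
    paste0("species_", seq_along(binary_maps))
  attr(out, "guild") <- guild
  class(out) <- c("richness_map", class(out))
  out
}

#' Richness surfaces per guild plus overall
#'
#' Splits the species maps by guild, stacks each guild, and stacks all
#' species together. Because the guilds partition the species, the overall
#' map equals the cellwise sum of the guild maps.
#'
#' @param binary_maps named list of aligned binary species maps.
#' @param guild_assignments named character vector (or tibble with
#'   `species_id` and `guild`) mapping each species to one of
#'   `"moss"`, `"liverwort"`, `"sphagna"`.
#' @param na_as_absence passed to [stack_richness()].
#' @return A named list of `richness_map`s: `all`, `moss`, `liverwort`,
#'   `sphagna` (a guild with no species yields an all-zero map).
#' @export
guild_richness <- function(binary_maps, guild_assignments,
                           na_as_absence = TRUE) {
  guilds_ok <- c("moss", "liverwort", "sphagna")
  if (is.data.frame(guild_assignments)) {
    ga <- stats::setNames(guild_assignments$guild,
                          guild_assignments$species_id)
  } else ga <- guild_assignments
  sp <- names(binary_maps)
  miss <- setdiff(sp, names(ga))
  if (length(miss))
    stop("no guild assignment for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(ga[sp]), guilds_ok)
  if (length(bad))
    stop("unknown guild label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  zero_map <- function() {
    template <- binary_maps[[1]]
    z <- unclass(template); z[] <- 0
    out <- as_result_layer(z, template)
    attr(out, "species") <- character(0)
    class(out) <- c("richness_map", class(out))
    out
  }
  out <- list(all = stack_richness(binary_maps, na_as_absence, guild = "all"))
  for (g in guilds_ok) {
    members <- sp[ga[sp] == g]
    out[[g]] <- if (length(members)) {
      stack_richness(binary_maps[members], na_as_absence, guild = g)
    } else {
      m <- zero_map(); attr(m, "guild") <- g; m
    }
  }
  out
}

#' @export
print.richness_map <- function(x, ...) {
  v <- unclass(x)
  cat("<richness_map> guild ", attr(x, "guild") %||% "all", ", ",
      length(attr(x, "species")), " species, richness range [",
      min(v, na.rm = TRUE), ", ", max(v, na.rm = TRUE), "]\n", sep = "")
  invisible(x)
}
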