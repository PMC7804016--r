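# Survey metadata for the 15 fenced South African reserves where brown
# hyaena camera-trap bycatch was analysed, and the array-design summaries.

#' Camera-trap survey table for the brown hyaena study reserves
#'
#' One row per fenced reserve: reserve size, minimum convex polygon of the
#' camera array, number of paired camera stations, and total trap nights.
#'
#' @return data frame with columns `site`, `reserve_size_km2`, `mcp_km2`,
#'   `stations`, `trap_nights`.
#' @export
hyaena_surveys <- function() {
  data.frame(
    site = c("Atherstone NR", "Dinokeng GR", "Ithala GR", "Khamab Kalahari",
             "Kwandwe PGR", "KwaZulu PGR", "Lapalala Wilderness", "Loskop Dam NR",
             "Madikwe GR", "Pilanesberg NP", "Songimvelo GR", "Venetia Limpopo NR",
             "Welgevonden PGR", "Wonderkop NR", "Zingela NR"),
    reserve_size_km2 = c(240, 185, 296, 955, 183, 185, 360, 232, 600, 550,
                         490, 316, 375, 160, 219),
    mcp_km2 = c(180, 173, 236, 570, 135, 135, 331, 170, 306, 247, 112, 237,
                203, 150, 177),
    stations = c(36, 36, 30, 37, 40, 34, 39, 34, 36, 40, 27, 39, 40, 37, 39),
    trap_nights = c(1797, 1586, 1315, 1744, 1860, 2645, 1932, 1774, 1472,
                    1785, 1127, 1934, 1292, 1579, 1690)
  )
}

#' Summarise a survey table
#'
#' Arithmetic means of reserve size, camera-array MCP, trap nights and
#' station count across sessions, rounded to the nearest integer for
#' reporting.
#'
#' @param table survey table as returned by [hyaena_surveys()] (columns
#'   `reserve_size_km2`, `mcp_km2`, `stations`, `trap_nights`).
#' @return named numeric vector of rounded means.
#' @export
survey_summary <- function(table = hyaena_surveys()) {
  need <- c("reserve_size_km2", "mcp_km2", "stations", "trap_nights")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(table[need])) stop("survey table has missing cells")
  c(reserve_size_km2 = round(mean(table$reserve_size_km2)),
    mcp_km2 = round(mean(table$mcp_km2)),
    trap_nights = round(mean(table$trap_nights)),
    stations = round(mean(table$stations)))
}

#' Maximum camera spacing supported by a home-range size
#'
#' Design check for SCR surveys: treating the smallest home range as a
#' circle of area `H`, its radius `sqrt(H / pi)` is the largest station
#' spacing that still guarantees every home range overlaps at least one
#' station. Reported to 2 decimals.
#'
#' @param home_range_km2 home-range area `H` in km^2 (> 0).
#' @return spacing in km, rounded to 2 dp.
#' @export
max_camera_spacing <- function(home_range_km2) {
  if (!is.numeric(home_range_km2) || any(home_range_km2 <= 0))
    stop("home-range area must be positive")
  round(sqrt(home_range_km2 / pi), 2)
}
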