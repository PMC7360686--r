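# Planted parameters per experimental condition and day in vitro.
# Calcium triplets (active fraction, events/min, duration s) are the printed
# group statistics where the source experiments report them; durations for
# conditions reported only as fold changes use that fold applied to the
# control duration. MEA columns are calibrated so n_hubs * burst_rate * 5 min
# lands on the group's small-burst count per 5 minutes, and hub out-degrees
# echo the reported hub connection counts.
preset_table <- function() {
  tibble::tribble(
    ~name,                  ~active_fraction, ~rate_per_min, ~duration_s,
    ~n_hubs, ~hub_out_degree, ~w,  ~burst_rate_per_min,
    "sham_DIV21",            0.8006, 2.30,  8.26, 5, 10, 0.8, 8.70,
    "sham_DIV28",            0.6870, 2.49,  6.20, 5, 10, 0.8, 10.15,
    "abeta_DIV21",           0.2901, 1.14, 12.80, 2,  3, 0.5, 7.43,
    "abeta_DIV28",           0.1718, 0.35, 13.24, 2,  3, 0.4, 5.01,
    "abeta_bdnf_DIV21",      0.6931, 2.38,  8.26, 4, 10, 0.7, 6.59,
    "abeta_aav_bdnf_DIV21",  0.7783, 1.76,  8.26, 4,  9, 0.7, 5.895,
    "control_DIV21",         0.7820, 1.94,  8.00, 5, 10, 0.8, 8.70,
    "fiveXFAD_DIV21",        0.4430, 1.16, 12.40, 3,  8, 0.6, 5.00,
    "control_DIV28",         0.6500, 2.64,  7.00, 5, 10, 0.8, 10.15,
    "fiveXFAD_DIV28",        0.3550, 1.44, 12.25, 3,  8, 0.6, 6.00
  )
}

#' Condition presets for the synthetic generators
#'
#' Returns the planted [network_spec()] and [calcium_spec()] for a named
#' experimental condition and day in vitro. The calcium parameters are set to
#' the group statistics reported for cultured hippocampal networks under each
#' condition (percent active cells, Ca2+ events/min, event duration); the MEA
#' parameters are calibrated so the expected small-network-burst count per
#' 5 minutes and the hub connection counts land on the corresponding group
#' values (e.g. `sham_DIV21` targets 217.5 small bursts/5 min with 5 hubs of
#' out-degree 10 at transmission probability 0.8).
#'
#' Available tokens: `sham_DIV21`, `sham_DIV28`, `abeta_DIV21`,
#' `abeta_DIV28`, `abeta_bdnf_DIV21`, `abeta_aav_bdnf_DIV21`,
#' `control_DIV21`, `control_DIV28`, `fiveXFAD_DIV21`, `fiveXFAD_DIV28`
#' (sham = vehicle for the amyloid-beta series; control = wild type for the
#' 5xFAD series).
#'
#' @param name A condition token (see above); unknown tokens raise an error
#'   listing the registry.
#' @param n_cells Number of cells for the calcium spec.
#' @return A list with `name`, `network` (a [network_spec()]) and `calcium`
#'   (a [calcium_spec()]).
#' @examples
#' p <- condition_preset("sham_DIV28")
#' p$calcium$event_rate_per_min  # 2.49
#' @export
condition_preset <- function(name, n_cells = 100) {
  reg <- preset_table()
  if (!is.character(name) || length(name) != 1 || !name %in% reg$name) {
    abort(paste0(
      "Unknown condition preset ", if (is.character(name)) paste0("'", name, "'") else "",
      ". Valid tokens: ", paste(reg$name, collapse = ", "), "."
    ))
  }
  row <- reg[reg$name == name, ]
  list(
    name = name,
    network = network_spec(
      n_electrodes = 59,
      n_hubs = row$n_hubs,
      hub_out_degree = row$hub_out_degree,
      w = row$w,
      burst_rate_per_min = row$burst_rate_per_min
    ),
    calcium = calcium_spec(
      n_cells = n_cells,
      active_fraction = row$active_fraction,
      event_rate_per_min = row$rate_per_min,
      event_duration_s = row$duration_s
    )
  )
}

#' @describeIn condition_preset The full preset registry as a tibble of
#'   planted parameters, one row per condition token.
#' @export
preset_registry <- function() preset_table()
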