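#' Unit conversion helpers
#'
#' Internal model units are centimetre-day-gram. Membrane permeabilities in
#' the plant-uptake literature are usually quoted in m s^-1; these helpers
#' convert between the two conventions.
#'
#' @param x numeric vector of values to convert.
#' @return numeric vector in the target unit.
#' @examples
#' ms_to_cmd(2.5e-4) # cell-wall permeability in cm/d
#' @export
ms_to_cmd <- function(x) x * 8.64e6

#' @rdname ms_to_cmd
#' @export
cmd_to_ms <- function(x) x / 8.64e6

# seconds per day * 100 cm/m = 8.64e6 is used throughout; keep one constant
SECONDS_PER_DAY_CM <- 8.64e6
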