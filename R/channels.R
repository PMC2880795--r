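#' Canonical 19-channel montage
#'
#' The frozen channel order used throughout the package for file round-trips
#' and matrix rows: the 19 electrodes of the International 10-20 system.
#'
#' @return Character vector of 19 channel names.
#' @export
#' @examples
#' erp_channels()
erp_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Schematic 2-D scalp coordinates (unit head circle, nose up) for the canonical
# montage; used to draw smooth focal topographies in the generator.
channel_coordinates <- function(channels = erp_channels()) {
  xy <- rbind(
    Fp1 = c(-0.31,  0.95), Fp2 = c( 0.31,  0.95),
    F7  = c(-0.81,  0.59), F3  = c(-0.40,  0.53), Fz = c(0.00, 0.55),
    F4  = c( 0.40,  0.53), F8  = c( 0.81,  0.59),
    T3  = c(-1.00,  0.00), C3  = c(-0.50,  0.00), Cz = c(0.00, 0.00),
    C4  = c( 0.50,  0.00), T4  = c( 1.00,  0.00),
    T5  = c(-0.81, -0.59), P3  = c(-0.40, -0.53), Pz = c(0.00, -0.55),
    P4  = c( 0.40, -0.53), T6  = c( 0.81, -0.59),
    O1  = c(-0.31, -0.95), O2  = c( 0.31, -0.95)
  )
  missing <- setdiff(channels, rownames(xy))
  if (length(missing)) {
    stop_erpica("no stored coordinates for channel(s): ",
                paste(missing, collapse = ", "))
  }
  xy[channels, , drop = FALSE]
}
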