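#' CSV round-trips for kernels and solutions
#'
#' Long-format CSV writers/readers.  Kernel CSV columns:
#' `(t, from_compartment, to_compartment, row_state, col_state, value)`
#' (scalar kernels have empty state columns).  Solution CSV columns:
#' `(t, compartment, N, B_total, D_total)`.  Floats are serialized with 17
#' significant digits so round-trips are lossless.
#'
#' @param x a `kernel_family` or `renewal_solution`.
#' @param path file path.
#' @name rfe_csv
NULL

write_csv17 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname rfe_csv
#' @export
write_kernel_csv <- function(x, path) {
  write_csv17(as.data.frame(x), path)
}

#' @rdname rfe_csv
#' @export
write_solution_csv <- function(x, path) {
  write_csv17(as.data.frame(x), path)
}

#' @rdname rfe_csv
#' @param grid `time_grid` the tabulated kernels are expected to live on
#'   (validated against the `t` column).
#' @export
read_kernel_csv <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(row_state = "character",
                                       col_state = "character"))
  df <- df[df$row_state == "" & df$col_state == "", , drop = FALSE]
  comp <- sort(unique(c(df$from_compartment, df$to_compartment)))
  np <- grid$n_points
  Phi <- array(0, dim = c(length(comp), length(comp), np),
               dimnames = list(comp, comp, NULL))
  for (a in comp) for (b in setdiff(comp, a)) {
    sub <- df[df$from_compartment == a & df$to_compartment == b, ]
    if (!nrow(sub)) next
    if (nrow(sub) != np || max(abs(sub$t - grid$t)) > 1e-9 * max(1, grid$t_end)) {
      stop("kernel CSV grid does not match the supplied time grid")
    }
    Phi[a, b, ] <- sub$value[order(sub$t)]
  }
  tabulated_kernels(Phi, grid)
}
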