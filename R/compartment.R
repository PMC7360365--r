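#' Define an enzymatic compartment
#'
#' A compartment (one Golgi cisterna type) holds a set of GTase rules and an
#' average residence time `T`. Under the `transport` exit model an oligomer's
#' residence time is exponentially distributed with mean `T` (oligomers are
#' ferried between cisternae); under `maturation` it is sharply peaked and
#' modeled as exactly `T` (the cisterna itself switches composition).
#' `T = Inf` means every oligomer reacts to a terminal state before exit.
#'
#' @param enzymes A list of [enzyme_rule()]s (a single enzyme is accepted).
#' @param residence_time Positive number or `Inf`.
#' @param exit_model `"transport"` (exponential exit) or `"maturation"`
#'   (fixed exit time).
#' @return A `glyc_compartment`.
#' @export
compartment <- function(enzymes, residence_time = Inf,
                        exit_model = c("transport", "maturation")) {
  if (inherits(enzymes, "glyc_enzyme")) enzymes <- list(enzymes)
  stopifnot(all(vapply(enzymes, inherits, logical(1), "glyc_enzyme")))
  exit_model <- match.arg(exit_model)
  if (!is.numeric(residence_time) || length(residence_time) != 1L ||
      is.na(residence_time) || residence_time <= 0) {
    stop("residence_time must be a positive number or Inf", call. = FALSE)
  }
  nms <- vapply(enzymes, function(e) e$name, character(1))
  if (anyDuplicated(nms)) {
    stop("enzyme names within a compartment must be unique", call. = FALSE)
  }
  structure(
    list(enzymes = rlang::set_names(enzymes, nms),
         residence_time = as.numeric(residence_time),
         exit_model = exit_model),
    class = "glyc_compartment"
  )
}

#' @export
print.glyc_compartment <- function(x, ...) {
  cat("<glyc_compartment> T = ", format(x$residence_time), " (",
      x$exit_model, "), ", length(x$enzymes), " enzymes\n", sep = "")
  for (e in x$enzymes) cat("  ", format(e), "\n", sep = "")
  invisible(x)
}

#' @export
format.glyc_compartment <- function(x, ...) {
  paste0("{", paste(names(x$enzymes), collapse = ", "), "} T=",
         format(x$residence_time))
}

# coerce a compartment or list of compartments to a series (list)
as_series <- function(series) {
  if (inherits(series, "glyc_compartment")) return(list(series))
  stopifnot(is.list(series),
            all(vapply(series, inherits, logical(1), "glyc_compartment")))
  series
}
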