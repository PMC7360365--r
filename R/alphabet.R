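#' Define a monomer alphabet
#'
#' A monomer alphabet lists the monosaccharide types available to a model:
#' each type has a name, a set of acceptor carbons (ring positions where a
#' branch may be attached) and a single donor carbon (the position the type
#' uses when it is itself attached as a branch). Real sugars differ in which
#' hydroxyls are available; here the carbon sets are an explicit modeling
#' choice and are fully user-configurable.
#'
#' @param types A character vector of type names, or a named list where each
#'   element is a list with fields `acceptor_carbons` (integer vector) and
#'   `donor_carbon` (integer scalar). When a plain character vector is given,
#'   every type receives `acceptor_carbons` and `donor_carbon`.
#' @param acceptor_carbons Default acceptor-carbon set applied to types given
#'   by name only. Default `c(2, 3, 4, 6)`, a common choice for hexoses.
#' @param donor_carbon Default donor carbon, default `1` (glycosidic bonds
#'   from the anomeric carbon).
#' @return An object of class `glyc_alphabet`: a named list of monomer type
#'   records.
#' @examples
#' ab <- monomer_alphabet(c("GlcNAc", "Gal", "Fuc"))
#' ab$Gal$acceptor_carbons
#' @export
monomer_alphabet <- function(types, acceptor_carbons = c(2L, 3L, 4L, 6L),
                             donor_carbon = 1L) {
  if (is.character(types)) {
    types <- rlang::set_names(
      lapply(types, function(nm) list(acceptor_carbons = as.integer(acceptor_carbons),
                                      donor_carbon = as.integer(donor_carbon))),
      types
    )
  }
  nms <- names(types)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("monomer type names must be nonempty and unique", call. = FALSE)
  }
  bad <- !grepl("^[A-Za-z][A-Za-z0-9]*$", nms)
  if (any(bad)) {
    stop("invalid monomer type name(s): ", paste(nms[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(nms, function(nm) {
    t <- types[[nm]]
    acc <- as.integer(t$acceptor_carbons %||% acceptor_carbons)
    don <- as.integer(t$donor_carbon %||% donor_carbon)
    if (length(acc) < 1L || any(acc <= 0L) || anyDuplicated(acc)) {
      stop("acceptor carbons of ", nm, " must be distinct positive integers",
           call. = FALSE)
    }
    if (length(don) != 1L || don <= 0L) {
      stop("donor carbon of ", nm, " must be a positive integer", call. = FALSE)
    }
    list(name = nm, acceptor_carbons = sort(acc), donor_carbon = don)
  })
  structure(rlang::set_names(out, nms), class = "glyc_alphabet")
}

#' Default monomer alphabet
#'
#' A small alphabet of common O-glycan monosaccharides (GalNAc, Gal, GlcNAc,
#' Fuc, Sia) with acceptor carbons `{2,3,4,6}` and donor carbon 1.
#'
#' @return A `glyc_alphabet`.
#' @export
default_alphabet <- function() {
  monomer_alphabet(c("GalNAc", "Gal", "GlcNAc", "Fuc", "Sia"))
}

#' @export
print.glyc_alphabet <- function(x, ...) {
  cat("<glyc_alphabet> ", length(x), " monomer types\n", sep = "")
  for (t in x) {
    cat(sprintf("  %-8s acceptor carbons {%s}, donor carbon %d\n",
                t$name, paste(t$acceptor_carbons, collapse = ","),
                t$donor_carbon))
  }
  invisible(x)
}

#' @export
format.glyc_alphabet <- function(x, ...) {
  paste0("<glyc_alphabet: ", paste(names(x), collapse = ", "), ">")
}

#' Read or write a monomer alphabet as YAML
#'
#' The YAML layout is a mapping from type name to `acceptor_carbons` and
#' `donor_carbon`, e.g.
#' ```yaml
#' Gal: {acceptor_carbons: [2, 3, 4, 6], donor_carbon: 1}
#' ```
#'
#' @param path File path.
#' @param alphabet A `glyc_alphabet`.
#' @return `read_alphabet()` returns a `glyc_alphabet`; `write_alphabet()`
#'   returns `path` invisibly.
#' @export
read_alphabet <- function(path) {
  monomer_alphabet(yaml::read_yaml(path))
}

#' @rdname read_alphabet
#' @export
write_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "glyc_alphabet"))
  yaml::write_yaml(
    lapply(alphabet, function(t) list(acceptor_carbons = t$acceptor_carbons,
                                      donor_carbon = t$donor_carbon)),
    path
  )
  invisible(path)
}
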