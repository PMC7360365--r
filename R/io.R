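#' Export results to plain-text formats
#'
#' Tabular results (distributions, entropy curves) are written as CSV;
#' structured reports (variability, plans) as JSON. All exports are
#' plain-text and round-trip friendly.
#'
#' @param x The object to export.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  df <- if (inherits(x, "glyc_distribution")) {
    as.data.frame(tidy(x))
  } else if (inherits(x, "glyc_entropy_curve")) {
    as.data.frame(x)
  } else {
    as.data.frame(x)
  }
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_csv
#' @export
export_json <- function(x, path) {
  obj <- if (inherits(x, "glyc_variability")) {
    list(
      causes = x$causes,
      loops = lapply(x$loops, function(l) list(types = l$types)),
      blocks = as.data.frame(x$blocks),
      truncation = x$truncation,
      stages = as.data.frame(x$stages)
    )
  } else if (inherits(x, "glyc_plan")) {
    list(
      feasible = x$feasible,
      n_compartments = x$n_compartments,
      input = serialize_canonical(x$input),
      target = serialize_canonical(x$target),
      stages = lapply(seq_len(nrow(x$stages)), function(k) {
        list(stage = k, output = x$stages$output[k],
             enzymes = x$stages$enzymes[[k]])
      })
    )
  } else if (inherits(x, "glyc_distribution")) {
    list(method = attr(x, "method"), seed = attr(x, "seed"),
         n_samples = attr(x, "n_samples"),
         probabilities = as.list(rlang::set_names(x$probability, x$oligomer)))
  } else {
    x
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' A scenario file bundles an alphabet, an enzyme library, a compartment
#' series and an input oligomer:
#'
#' ```yaml
#' alphabet:
#'   GlcNAc: {acceptor_carbons: [2,3,4,6], donor_carbon: 1}
#'   Gal:    {acceptor_carbons: [2,3,4,6], donor_carbon: 1}
#' enzymes:
#'   - {name: Fut2cf, class: cf, donor_type: Fuc, acceptor_type: Gal,
#'      acceptor_carbon: 2}
#' series:
#'   - {enzymes: [Fut2cf], residence_time: .inf, exit_model: transport}
#' input: Gal(3-1)GlcNAc
#' ```
#'
#' @param path YAML file path.
#' @return A list with `alphabet`, `library`, `series`, `input`, and
#'   `target` (when present).
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  alphabet <- monomer_alphabet(cfg$alphabet)
  library <- lapply(cfg$enzymes, function(en) {
    enzyme_rule(
      name = en$name, donor_type = en$donor_type,
      acceptor_type = en$acceptor_type, acceptor_carbon = en$acceptor_carbon,
      donor_carbon = en$donor_carbon, class = en$class,
      required_branches = en$required_branches %||% list(),
      forbidden_branches = en$forbidden_branches %||% list(),
      root_chain = en$root_chain %||% list(),
      concentration = en$concentration %||% 1,
      alphabet = alphabet
    )
  })
  names(library) <- vapply(library, function(e) e$name, character(1))
  series <- lapply(cfg$series %||% list(), function(st) {
    compartment(
      unname(library[unlist(st$enzymes)]),
      residence_time = if (is.null(st$residence_time)) Inf
                       else as.numeric(st$residence_time),
      exit_model = st$exit_model %||% "transport"
    )
  })
  list(
    alphabet = alphabet,
    library = unname(library),
    series = series,
    input = if (!is.null(cfg$input)) parse_oligomer(cfg$input, alphabet),
    target = if (!is.null(cfg$target)) parse_oligomer(cfg$target, alphabet)
  )
}
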