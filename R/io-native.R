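#' Write a model in the native JSON dialect
#'
#' The dialect is a single JSON object with top-level keys `metabolites`,
#' `reactions`, `roles` and `provenance`. Metabolite `formula` and reaction
#' `stoichiometry` are JSON objects (element/metabolite -> number); bounds
#' are explicit numbers. Field order is fixed, so serialising the same model
#' twice yields byte-identical files.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_native_model <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    f <- m$formula[[1]]
    list(
      id = m$id, name = m$name,
      formula = if (is.null(f)) NULL else as.list(f),
      charge = m$charge, compartment = m$compartment
    )
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    list(
      id = r$id, name = r$name,
      stoichiometry = as.list(r$stoichiometry[[1]]),
      lower_bound = r$lower_bound, upper_bound = r$upper_bound,
      is_exchange = r$is_exchange
    )
  })
  obj <- list(metabolites = mets, reactions = rxns,
              roles = model$roles, provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a model from the native JSON dialect
#'
#' @param path File written by [write_native_model()] (or authored by hand in
#'   the same schema).
#' @return A `metabolic_model`.
#' @export
read_native_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("metabolites", "reactions")) {
    if (is.null(obj[[key]])) {
      abort(paste0("native model file missing required key: '", key, "'"))
    }
  }
  req_met <- c("id", "compartment")
  mets <- dplyr::bind_rows(lapply(obj$metabolites, function(m) {
    miss <- setdiff(req_met, names(m))
    if (length(miss)) abort(paste0("metabolite entry missing key: '",
                                   miss[1], "'"))
    metabolite(
      id = m$id, name = m$name %||% m$id,
      formula = if (is.null(m$formula)) NULL else
        unlist(lapply(m$formula, as.numeric)),
      charge = m$charge %||% 0L, compartment = m$compartment
    )
  }))
  req_rxn <- c("id", "stoichiometry", "lower_bound", "upper_bound")
  rxns <- dplyr::bind_rows(lapply(obj$reactions, function(r) {
    miss <- setdiff(req_rxn, names(r))
    if (length(miss)) abort(paste0("reaction entry missing key: '",
                                   miss[1], "'"))
    reaction(
      id = r$id, name = r$name %||% r$id,
      stoichiometry = unlist(lapply(r$stoichiometry, as.numeric)),
      lower_bound = r$lower_bound, upper_bound = r$upper_bound,
      is_exchange = r$is_exchange %||% FALSE
    )
  }))
  metabolic_model(mets, rxns, roles = lapply(obj$roles, as.character),
                  provenance = obj$provenance %||% "")
}

names2 <- function(x) names(x) %||% character(length(x))

#' Test two models for equality of content
#'
#' Compares metabolites, reactions (including bounds and stoichiometry),
#' roles and provenance, ignoring attribute bookkeeping.
#'
#' @param a,b `metabolic_model` objects.
#' @param tol Numeric tolerance on coefficients and bounds.
#' @return TRUE/FALSE.
#' @export
models_equal <- function(a, b, tol = 1e-12) {
  if (!identical(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!identical(a$reactions$id, b$reactions$id)) return(FALSE)
  for (i in seq_len(nrow(a$metabolites))) {
    fa <- a$metabolites$formula[[i]]; fb <- b$metabolites$formula[[i]]
    if (is.null(fa) != is.null(fb)) return(FALSE)
    if (!is.null(fa)) {
      fa <- fa[order(names(fa))]; fb <- fb[order(names(fb))]
      if (!identical(names(fa), names(fb)) || any(abs(fa - fb) > tol)) {
        return(FALSE)
      }
    }
  }
  if (any(abs(a$reactions$lower_bound - b$reactions$lower_bound) > tol)) return(FALSE)
  if (any(abs(a$reactions$upper_bound - b$reactions$upper_bound) > tol)) return(FALSE)
  for (i in seq_len(nrow(a$reactions))) {
    sa <- a$reactions$stoichiometry[[i]]; sb <- b$reactions$stoichiometry[[i]]
    sa <- sa[order(names(sa))]; sb <- sb[order(names(sb))]
    if (!identical(names(sa), names(sb)) || any(abs(sa - sb) > tol)) {
      return(FALSE)
    }
  }
  ra <- lapply(a$roles, as.character)
  rb <- lapply(b$roles, as.character)
  identical(ra[order(names2(ra))], rb[order(names2(rb))]) &&
    identical(a$provenance, b$provenance)
}
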