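# Enzyme ruleset configuration.
#
# Ruleset schema (YAML):
#   name: <ruleset label>
#   enzymes:
#     <enzyme name>:
#       ec: <EC number>
#       rules:
#         - P1:   {allow: KR}      # residue sets as letter strings
#           "P1'": {deny: P}
#
# Every rule must constrain P1; `allow`/`deny` sets are non-empty subsets
# of the 20-letter alphabet. Rulesets are data: the bundled `biopep_2020`
# file transcribes published qualitative specificities for the six default
# enzymes and can be replaced by any file in the same schema.

#' Parse an enzyme ruleset file
#'
#' @param path YAML ruleset in the documented schema.
#' @return Named list of [enzyme_spec()] objects; the ruleset label is kept
#'   in attribute `"name"`.
#' @export
parse_ruleset <- function(path) {
  if (!file.exists(path)) stop("ruleset file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$enzymes) || !length(doc$enzymes)) {
    stop("ruleset has no 'enzymes' section: ", path)
  }
  if (is.null(names(doc$enzymes)) || any(!nzchar(names(doc$enzymes)))) {
    stop("every enzyme entry must be named")
  }
  if (anyDuplicated(names(doc$enzymes))) {
    stop("duplicate enzyme name(s): ",
         paste(unique(names(doc$enzymes)[duplicated(names(doc$enzymes))]),
               collapse = ", "))
  }
  specs <- lapply(names(doc$enzymes), function(nm) {
    entry <- doc$enzymes[[nm]]
    rules <- entry$rules
    if (is.null(rules) || !length(rules)) {
      stop("enzyme '", nm, "' has an empty rule list")
    }
    parsed <- lapply(seq_along(rules), function(i) {
      r <- rules[[i]]
      if (is.null(names(r)) || any(!nzchar(names(r)))) {
        stop("enzyme '", nm, "', rule ", i, ": positions must be named")
      }
      cons <- lapply(names(r), function(pos) {
        spec <- r[[pos]]
        if (!is.list(spec) || length(spec) != 1L ||
            !names(spec) %in% c("allow", "deny")) {
          stop("enzyme '", nm, "', rule ", i, ", position ", pos,
               ": constraint must be a single allow: or deny: entry")
        }
        set <- as.character(spec[[1]])
        con <- tryCatch(
          if (names(spec) == "allow") allow(set) else deny(set),
          error = function(e) {
            stop("enzyme '", nm, "', rule ", i, ", position ", pos, ": ",
                 conditionMessage(e), call. = FALSE)
          })
        con
      })
      names(cons) <- names(r)
      tryCatch(do.call(cleavage_rule, cons), error = function(e) {
        stop("enzyme '", nm, "', rule ", i, ": ", conditionMessage(e),
             call. = FALSE)
      })
    })
    enzyme_spec(nm, ec_number = entry$ec %||% NA_character_, rules = parsed)
  })
  names(specs) <- names(doc$enzymes)
  attr(specs, "name") <- doc$name %||% basename(path)
  specs
}

#' The bundled default ruleset
#'
#' Loads the `biopep_2020` ruleset shipped with the package: positional
#' specificities for stem bromelain, ficin, papain, pepsin, trypsin and
#' chymotrypsin, transcribed from published qualitative specificity
#' summaries. See the methods vignette for the provenance and the
#' transcription caveats of each entry.
#'
#' @return Named list of [enzyme_spec()] objects.
#' @export
default_ruleset <- function() {
  parse_ruleset(system.file("extdata", "rulesets", "biopep_2020.yaml",
                            package = "biopepsim", mustWork = TRUE))
}

#' Resolve enzyme names against a ruleset
#'
#' @param names Character vector of enzyme names.
#' @param ruleset Named list of [enzyme_spec()], e.g. [default_ruleset()].
#' @return List of `enzyme_spec` objects in the order given.
#' @export
resolve_enzymes <- function(names, ruleset = default_ruleset()) {
  stopifnot(is.character(names), length(names) >= 1L)
  missing_enz <- setdiff(names, base::names(ruleset))
  if (length(missing_enz)) {
    stop("enzyme(s) not in ruleset '", attr(ruleset, "name") %||% "?", "': ",
         paste(missing_enz, collapse = ", "))
  }
  ruleset[names]
}
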