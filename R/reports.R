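# JSON / TSV report plumbing.

#' Serialize a verdict (with its trigger state) to JSON
#'
#' @param v a `verdict`
#' @param path output file; when `NULL` the JSON string is returned
#' @param ligand_name optional ligand name to embed
#' @return `path` (invisibly) or the JSON string
#' @export
write_verdict_json <- function(v, path = NULL, ligand_name = NULL) {
  stopifnot(inherits(v, "verdict"))
  obj <- list(
    ligand = ligand_name,
    category = v$category,
    score = v$score,
    predicted_sites = v$predicted_sites,
    failed_rules = v$failed_rules,
    trigger = list(final_ring = v$trigger$final_ring,
                   fastened = v$trigger$fastened,
                   contacted_atoms = v$trigger$contacted_atoms,
                   pillar_support = v$trigger$pillar_support,
                   path_taken = v$trigger$path_taken),
    rules = lapply(v$rule_results, function(r)
      list(passed = r$passed, note = r$note,
           evidence = r$evidence))
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write a rule matrix as TSV
#'
#' @param v a `verdict` (or a data frame already shaped like
#'   [verdict_table()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_rule_matrix_tsv <- function(v, path) {
  tab <- if (inherits(v, "verdict")) verdict_table(v) else v
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize an annotated ligand graph to JSON
#'
#' @param g a `ligand_graph`
#' @param path output file; when `NULL` the JSON string is returned
#' @return `path` (invisibly) or the JSON string
#' @export
write_ligand_json <- function(g, path = NULL) {
  stopifnot(inherits(g, "ligand_graph"))
  obj <- list(name = g$name, atoms = g$atoms, bonds = g$bonds,
              annotations = g$annotations)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}
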