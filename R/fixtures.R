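fixture_md5 <- c(
  table1 = "5d9ec24a39c159a8ae2fdc24b1d6a0e4",
  table2 = "de0711051311c4b531319d99f4996ca4",
  table3 = "8d288772dfc727cda51dc01378e11892"
)

#' Load a packaged group-results fixture
#'
#' Three small CSV fixtures ship with the package, holding the printed
#' group tables of the study the simulations emulate:
#' \describe{
#'   \item{`table1`}{stereo threshold group means/SDs at baseline and
#'     under 10--40 percent dominant-eye contrast decrements, with
#'     relative changes and versus-baseline flags (n = 19 normal
#'     observers).}
#'   \item{`table2`}{interocular VA, CR and stereo threshold group
#'     means/SDs at baseline and under the five Bangerter filter
#'     levels.}
#'   \item{`table3`}{seven individual amblyopic observers: CR, baseline
#'     stereo threshold, and thresholds with the dominant eye contrast
#'     reduced by CR, CR+25 percent CR and CR-25 percent CR.}
#' }
#' Files are checksummed on load; a mismatch is a hard failure so
#' fixture values can never silently drift.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return a data frame of the printed values.
#' @examples
#' load_fixture("table3")
#' @export
load_fixture <- function(name) {
  if (!name %in% names(fixture_md5)) stop("unknown fixture: ", name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "dichoptr",
                      mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(fixture_md5[name])))
    stop("fixture checksum mismatch for ", name, ": file corrupted")
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
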