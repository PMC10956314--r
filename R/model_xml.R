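## XML model dialect (self-defined, documented in ?parseModel).
## Serialization is deterministic: fixed element order, fixed attribute
## order, shortest exactly-round-tripping number format; empty optional
## sections are omitted. write(parse(write(m))) == write(m) byte-for-byte.

.fmtNum <- function(x) {
  vapply(x, function(v) {
    s <- as.character(v)
    if (identical(as.numeric(s), as.numeric(v))) s else sprintf("%.17g", v)
  }, character(1))
}

.fmtBool <- function(x) ifelse(x, "true", "false")

.fmtConstraints <- function(v, bound = c("bound", "empty")) {
  if (!length(v)) return(NULL)
  paste(sprintf("%s=%s", names(v), ifelse(v, bound[1L], bound[2L])), collapse = ",")
}

.parseConstraints <- function(s, bound = c("bound", "empty")) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(logical())
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- vapply(parts, function(p) {
    if (length(p) != 2L || !p[2L] %in% bound)
      stop(sprintf("malformed site/state constraint '%s'", paste(p, collapse = "=")))
    p[2L] == bound[1L]
  }, logical(1))
  names(vals) <- vapply(parts, `[[`, character(1), 1L)
  vals
}

.xAttr <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

.xNum <- function(node, name, default = NULL) {
  v <- .xAttr(node, name)
  if (is.null(v)) {
    if (is.null(default)) stop(sprintf("missing attribute '%s' on <%s>", name, xml2::xml_name(node)))
    return(default)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) stop(sprintf("attribute '%s' on <%s> is not numeric: '%s'",
                               name, xml2::xml_name(node), v))
  out
}

.xBool <- function(node, name, default = FALSE) {
  v <- .xAttr(node, name)
  if (is.null(v)) default else identical(v, "true")
}

.voxelChildren <- function(node) {
  vs <- xml2::xml_find_all(node, "./voxel")
  if (!length(vs)) return(matrix(integer(), 0L, 3L, dimnames = list(NULL, c("i","j","k"))))
  m <- cbind(i = as.integer(xml2::xml_attr(vs, "i")),
             j = as.integer(xml2::xml_attr(vs, "j")),
             k = as.integer(xml2::xml_attr(vs, "k")))
  if (anyNA(m)) stop("malformed <voxel> element: attributes i, j, k required")
  m
}

#' Read a model from its XML description
#'
#' Parses the package's XML model dialect into a [SimModel-class], fills
#' defaults for omitted optional elements (no sources, no microdomains, no
#' immobilizations, log interval 1, particle logging off, seed 0) and
#' validates the result; any cross-reference or range violation is raised
#' as an error naming the offending element.
#'
#' @section Dialect:
#' Root `<cell4d-model>` with children, in order:
#' \itemize{
#' \item `<environment nx= ny= nz= voxel_len= timestep= n_steps= seed=/>`
#' \item `<compartments>` containing `<compartment name= membrane_2d=
#'   parent=>` with `<box x0= x1= y0= y1= z0= z1=/>` (0-based half-open
#'   voxel index ranges) and/or `<voxel i= j= k=/>` children.
#' \item one `<species name= kind= D= membrane_bound=>` per species, with
#'   `<site name=/>`, `<state name=/>` and `<allowed compartment=/>` children.
#' \item `<reactions>` containing `<reaction id= k= reversible= k_rev=
#'   compartments= sigma_u_mult=>` with `<reactant species= sites= states=/>`
#'   and `<product .../>` children; `sites="N1=bound,N2=empty"` and
#'   `states="phos=true"` encode pattern constraints.
#' \item `<transports>` with `<transport id= species= from= to= prob=
#'   blocked_by= sites= states=/>`.
#' \item `<sources>` with `<source species= mode= value=>` and voxel children.
#' \item `<microdomains>` with `<domain name=>` containing voxel children and
#'   `<partition species= entry= exit=/>` rows.
#' \item `<immobilizations>` with `<immobilization id= species= k_on= k_off=
#'   compartments= sites= states=/>`.
#' \item one `<initial species= amount= value= compartment=/>` per initial
#'   condition (`amount` is `"count"` or `"concentration"`).
#' \item `<output log_interval= particle_log= per_compartment=/>`.
#' }
#' Units: lengths um, time s, concentrations mol/L, unimolecular rates
#' s^-1, bimolecular rates M^-1 s^-1.
#'
#' @param xml XML text, a file path, or an `xml2` document.
#' @return a validated [SimModel-class].
#' @seealso [writeModel()], [validateModel()]
#' @export
parseModel <- function(xml) {
  doc <- tryCatch(
    if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml),
    error = function(e) stop("XML parse error: ", conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "cell4d-model")
    stop("root element must be <cell4d-model>")

  env <- xml2::xml_find_first(root, "./environment")
  if (inherits(env, "xml_missing")) stop("missing <environment> element")
  environment <- newEnvironment(
    nx = .xNum(env, "nx"), ny = .xNum(env, "ny"), nz = .xNum(env, "nz"),
    voxelLen = .xNum(env, "voxel_len"), timestep = .xNum(env, "timestep"),
    nSteps = .xNum(env, "n_steps"), seed = .xNum(env, "seed", 0))

  compartments <- lapply(xml2::xml_find_all(root, "./compartments/compartment"), function(cn) {
    bs <- xml2::xml_find_all(cn, "./box")
    boxes <- if (length(bs)) {
      t(vapply(bs, function(b) vapply(c("x0","x1","y0","y1","z0","z1"),
                                      function(a) .xNum(b, a), numeric(1)), numeric(6)))
    } else NULL
    newCompartment(name = .xAttr(cn, "name", stop("compartment missing name")),
                   boxes = boxes, voxels = .voxelChildren(cn),
                   parent = .xAttr(cn, "parent", NA_character_),
                   membrane2d = .xBool(cn, "membrane_2d"))
  })

  species <- lapply(xml2::xml_find_all(root, "./species"), function(sn) {
    newSpecies(name = .xAttr(sn, "name", stop("species missing name")),
               kind = .xAttr(sn, "kind", "particle"), D = .xNum(sn, "D"),
               sites = xml2::xml_attr(xml2::xml_find_all(sn, "./site"), "name"),
               states = xml2::xml_attr(xml2::xml_find_all(sn, "./state"), "name"),
               allowed = xml2::xml_attr(xml2::xml_find_all(sn, "./allowed"), "compartment"),
               membraneBound = .xBool(sn, "membrane_bound"))
  })

  parsePat <- function(pn)
    rxPattern(.xAttr(pn, "species", stop("pattern missing species")),
              sites = .parseConstraints(.xAttr(pn, "sites"), c("bound", "empty")),
              states = .parseConstraints(.xAttr(pn, "states"), c("true", "false")))
  parseScope <- function(s) if (is.null(s) || !nzchar(s)) character() else
    strsplit(s, " ", fixed = TRUE)[[1L]]

  reactions <- lapply(xml2::xml_find_all(root, "./reactions/reaction"), function(rn) {
    newReaction(id = .xAttr(rn, "id", stop("reaction missing id")),
                reactants = lapply(xml2::xml_find_all(rn, "./reactant"), parsePat),
                products = lapply(xml2::xml_find_all(rn, "./product"), parsePat),
                k = .xNum(rn, "k"), reversible = .xBool(rn, "reversible"),
                kRev = .xNum(rn, "k_rev", 0),
                compartments = parseScope(.xAttr(rn, "compartments")),
                sigmaUMult = .xNum(rn, "sigma_u_mult", 1))
  })

  transports <- lapply(xml2::xml_find_all(root, "./transports/transport"), function(tn) {
    newTransport(id = .xAttr(tn, "id", stop("transport missing id")),
                 species = .xAttr(tn, "species"), from = .xAttr(tn, "from"),
                 to = .xAttr(tn, "to"), prob = .xNum(tn, "prob"),
                 blockedBy = .xAttr(tn, "blocked_by", NA_character_),
                 sites = .parseConstraints(.xAttr(tn, "sites"), c("bound", "empty")),
                 states = .parseConstraints(.xAttr(tn, "states"), c("true", "false")))
  })

  sources <- lapply(xml2::xml_find_all(root, "./sources/source"), function(sn) {
    newSourceSink(species = .xAttr(sn, "species"), voxels = .voxelChildren(sn),
                  mode = .xAttr(sn, "mode", "clamp"), value = .xNum(sn, "value", 0))
  })

  microdomains <- lapply(xml2::xml_find_all(root, "./microdomains/domain"), function(dn) {
    ps <- xml2::xml_find_all(dn, "./partition")
    part <- data.frame(species = xml2::xml_attr(ps, "species"),
                       entry = as.numeric(xml2::xml_attr(ps, "entry")),
                       exit = as.numeric(xml2::xml_attr(ps, "exit")))
    newMicrodomain(name = .xAttr(dn, "name", stop("domain missing name")),
                   voxels = .voxelChildren(dn), partition = part)
  })

  immobilizations <- lapply(xml2::xml_find_all(root, "./immobilizations/immobilization"),
                            function(mn) {
    newImmobilization(id = .xAttr(mn, "id", stop("immobilization missing id")),
                      species = .xAttr(mn, "species"), kOn = .xNum(mn, "k_on"),
                      kOff = .xNum(mn, "k_off"),
                      compartments = parseScope(.xAttr(mn, "compartments")),
                      sites = .parseConstraints(.xAttr(mn, "sites"), c("bound", "empty")),
                      states = .parseConstraints(.xAttr(mn, "states"), c("true", "false")))
  })

  ins <- xml2::xml_find_all(root, "./initial")
  initials <- data.frame(
    species = xml2::xml_attr(ins, "species"),
    amount = vapply(ins, function(n) .xAttr(n, "amount", "count"), character(1)),
    value = as.numeric(xml2::xml_attr(ins, "value")),
    compartment = xml2::xml_attr(ins, "compartment"))

  outn <- xml2::xml_find_first(root, "./output")
  logInterval <- 1L; particleLogFlag <- FALSE; perComp <- FALSE
  if (!inherits(outn, "xml_missing")) {
    logInterval <- as.integer(.xNum(outn, "log_interval", 1))
    particleLogFlag <- .xBool(outn, "particle_log")
    perComp <- .xBool(outn, "per_compartment")
  }

  model <- newSimModel(environment = environment, compartments = compartments,
                       species = species, reactions = reactions,
                       transports = transports, sources = sources,
                       microdomains = microdomains,
                       immobilizations = immobilizations, initials = initials,
                       logInterval = logInterval, particleLog = particleLogFlag,
                       perCompartment = perComp)
  .assertValid(model)
  model
}

#' Serialize a model to XML text
#'
#' Deterministic serialization (stable element and attribute order, exact
#' number round-tripping); empty optional sections are omitted. The output
#' is parseable by [parseModel()] and `writeModel(parseModel(writeModel(m)))`
#' is byte-identical to `writeModel(m)`.
#'
#' @param model a valid [SimModel-class].
#' @param file optional path; when given the XML is also written there.
#' @return the XML text, invisibly when `file` is given.
#' @export
writeModel <- function(model, file = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- character()
  emit <- function(...) lines[[length(lines) + 1L]] <<- paste0(...)
  tag <- function(name, attrs, close = TRUE, indent = 0) {
    attrs <- attrs[!vapply(attrs, is.null, logical(1))]
    a <- paste(sprintf('%s="%s"', names(attrs), esc(unlist(attrs))), collapse = " ")
    emit(strrep("  ", indent), "<", name, if (nzchar(a)) paste0(" ", a),
         if (close) "/", ">")
  }
  voxTags <- function(vox, indent) for (r in seq_len(nrow(vox)))
    tag("voxel", list(i = vox[r, 1L], j = vox[r, 2L], k = vox[r, 3L]), TRUE, indent)
  patAttrs <- function(p) list(species = p$species,
                               sites = .fmtConstraints(p$sites, c("bound", "empty")),
                               states = .fmtConstraints(p$states, c("true", "false")))
  scopeAttr <- function(s) if (length(s)) paste(s, collapse = " ") else NULL

  e <- model@environment
  emit("<cell4d-model>")
  tag("environment", list(nx = e@nx, ny = e@ny, nz = e@nz,
                          voxel_len = .fmtNum(e@voxelLen),
                          timestep = .fmtNum(e@timestep),
                          n_steps = e@nSteps, seed = e@seed), TRUE, 1)
  emit("  <compartments>")
  for (cp in model@compartments) {
    tag("compartment", list(name = cp@name,
                            membrane_2d = if (cp@membrane2d) "true" else NULL,
                            parent = if (!is.na(cp@parent)) cp@parent else NULL),
        close = FALSE, indent = 2)
    for (r in seq_len(nrow(cp@boxes)))
      tag("box", as.list(structure(.fmtNum(cp@boxes[r, ]),
                                   names = c("x0","x1","y0","y1","z0","z1"))), TRUE, 3)
    voxTags(cp@voxels, 3)
    emit("    </compartment>")
  }
  emit("  </compartments>")
  for (sp in model@species) {
    tag("species", list(name = sp@name, kind = sp@kind, D = .fmtNum(sp@D),
                        membrane_bound = if (sp@membraneBound) "true" else NULL),
        close = FALSE, indent = 1)
    for (s in sp@sites) tag("site", list(name = s), TRUE, 2)
    for (s in sp@states) tag("state", list(name = s), TRUE, 2)
    for (a in sp@allowed) tag("allowed", list(compartment = a), TRUE, 2)
    emit("  </species>")
  }
  if (length(model@reactions)) {
    emit("  <reactions>")
    for (rx in model@reactions) {
      tag("reaction", list(id = rx@id, k = .fmtNum(rx@k),
                           reversible = if (rx@reversible) "true" else NULL,
                           k_rev = if (rx@reversible) .fmtNum(rx@kRev) else NULL,
                           compartments = scopeAttr(rx@compartments),
                           sigma_u_mult = if (rx@sigmaUMult != 1) .fmtNum(rx@sigmaUMult) else NULL),
          close = FALSE, indent = 2)
      for (p in rx@reactants) tag("reactant", patAttrs(p), TRUE, 3)
      for (p in rx@products) tag("product", patAttrs(p), TRUE, 3)
      emit("    </reaction>")
    }
    emit("  </reactions>")
  }
  if (length(model@transports)) {
    emit("  <transports>")
    for (tr in model@transports)
      tag("transport", c(list(id = tr@id, species = tr@species, from = tr@from,
                              to = tr@to, prob = .fmtNum(tr@prob),
                              blocked_by = if (!is.na(tr@blockedBy)) tr@blockedBy else NULL),
                         list(sites = .fmtConstraints(tr@sites, c("bound", "empty")),
                              states = .fmtConstraints(tr@states, c("true", "false")))),
          TRUE, 2)
    emit("  </transports>")
  }
  if (length(model@sources)) {
    emit("  <sources>")
    for (ss in model@sources) {
      tag("source", list(species = ss@species, mode = ss@mode,
                         value = .fmtNum(ss@value)), close = FALSE, indent = 2)
      voxTags(ss@voxels, 3)
      emit("    </source>")
    }
    emit("  </sources>")
  }
  if (length(model@microdomains)) {
    emit("  <microdomains>")
    for (md in model@microdomains) {
      tag("domain", list(name = md@name), close = FALSE, indent = 2)
      voxTags(md@voxels, 3)
      for (r in seq_len(nrow(md@partition)))
        tag("partition", list(species = md@partition$species[r],
                              entry = .fmtNum(md@partition$entry[r]),
                              exit = .fmtNum(md@partition$exit[r])), TRUE, 3)
      emit("    </domain>")
    }
    emit("  </microdomains>")
  }
  if (length(model@immobilizations)) {
    emit("  <immobilizations>")
    for (im in model@immobilizations)
      tag("immobilization", list(id = im@id, species = im@species,
                                 k_on = .fmtNum(im@kOn), k_off = .fmtNum(im@kOff),
                                 compartments = scopeAttr(im@compartments),
                                 sites = .fmtConstraints(im@sites, c("bound", "empty")),
                                 states = .fmtConstraints(im@states, c("true", "false"))),
          TRUE, 2)
    emit("  </immobilizations>")
  }
  for (r in seq_len(nrow(model@initials))) {
    ini <- model@initials[r, ]
    tag("initial", list(species = ini$species, amount = ini$amount,
                        value = .fmtNum(ini$value), compartment = ini$compartment), TRUE, 1)
  }
  o <- model@output
  tag("output", list(log_interval = o$logInterval,
                     particle_log = .fmtBool(isTRUE(o$particleLog)),
                     per_compartment = .fmtBool(isTRUE(o$perCompartment))), TRUE, 1)
  emit("</cell4d-model>")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

## short content hash (two independent 31-bit polynomial rolling hashes)
## of the canonical XML; used for result provenance only
.modelHash <- function(model) {
  bytes <- utf8ToInt(writeModel(model))
  m <- 2147483629; h1 <- 1; h2 <- 2
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% m
    h2 <- (h2 * 137 + b) %% m
  }
  sprintf("%08x%08x", h1, h2)
}
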