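test_that("single producer and double receptor give one edge of weight 2", {
    calls <- makeCalls(ligands = list(T1 = "LX", T2 = character(0)),
                       receptors = list(T1 = character(0),
                                        T2 = c("R1", "R2")))
    lr <- LRInteractionTable(ligand = c("LX", "LX"),
                             receptor = c("R1", "R2"))
    net <- buildNetwork(calls, lr, includeOthers = FALSE)
    expect_identical(ligandNodes(net), "LX")
    expect_equal(productionMatrix(net)["T1", "LX"], 1)
    expect_equal(bindingMatrix(net)["LX", "T2"], 2L)
    expect_equal(bindingMatrix(net)["LX", "T1"], 0L)
})

test_that("orphan ligands route through the Others node", {
    # receptor expressed, no modeled producer -> Others -> cell
    calls <- makeCalls(ligands = list(T1 = character(0)),
                       receptors = list(T1 = "KIT"))
    lr <- LRInteractionTable(ligand = "KITLG", receptor = "KIT")
    net <- buildNetwork(calls, lr, includeOthers = TRUE)
    expect_true("Others" %in% cellTypes(net))
    expect_equal(productionMatrix(net)["Others", "KITLG"], 1)
    expect_equal(bindingMatrix(net)["KITLG", "T1"], 1L)
    # produced but bound by no modeled cell -> absorbed by Others
    calls2 <- makeCalls(ligands = list(T1 = "LY"),
                        receptors = list(T1 = character(0)))
    lr2 <- LRInteractionTable(ligand = "LY", receptor = "RY")
    net2 <- buildNetwork(calls2, lr2, includeOthers = TRUE)
    expect_equal(bindingMatrix(net2)["LY", "Others"], 1L)
    # neither producer nor binder -> dropped
    net3 <- buildNetwork(makeCalls(ligands = list(T1 = character(0)),
                                   receptors = list(T1 = character(0))),
                         lr2, includeOthers = TRUE)
    expect_length(ligandNodes(net3), 0L)
})

test_that("heteromeric mode counts complexes once and only when complete", {
    lr <- readLRTable(system.file("extdata", "example_lr_heteromeric.tsv",
                                  package = "hemaCCC"))
    # only one of the two IL6 complex subunits expressed
    calls1 <- makeCalls(ligands = list(T1 = "IL6"),
                        receptors = list(T2 = "IL6R"))
    nInd <- buildNetwork(calls1, lr, heteromericMode = FALSE,
                         includeOthers = FALSE)
    nHet <- buildNetwork(calls1, lr, heteromericMode = TRUE,
                         includeOthers = TRUE)
    expect_equal(bindingMatrix(nInd)["IL6", "T2"], 1L)
    expect_equal(bindingMatrix(nHet)["IL6", "T2"], 0L)
    # both subunits expressed: complex counts once (not twice)
    calls2 <- makeCalls(ligands = list(T1 = "IL6"),
                        receptors = list(T2 = c("IL6R", "IL6ST")))
    expect_equal(bindingMatrix(
        buildNetwork(calls2, lr, heteromericMode = TRUE,
                     includeOthers = FALSE))["IL6", "T2"], 1L)
    expect_equal(bindingMatrix(
        buildNetwork(calls2, lr, heteromericMode = FALSE,
                     includeOthers = FALSE))["IL6", "T2"], 2L)
})

test_that("heteromeric mode never increases a binding entry", {
    d <- syntheticDesign(seed = 61L, nLigandGenes = 10L,
                         nReplicatesPerType = 3L)
    dat <- generateExpression(d)
    lr0 <- generateLRTable(d)
    # declare every multi-receptor ligand's receptors one complex
    p <- interactions(lr0)
    grp <- ave(p$ligand, p$ligand, FUN = length)
    lr <- LRInteractionTable(p$ligand, p$receptor,
                             heteromericGroup = ifelse(
                                 grp >= 2, paste0(p$ligand, "_c"), NA))
    calls <- callOverexpressed(dat, lr)
    bInd <- bindingMatrix(buildNetwork(calls, lr,
                                       heteromericMode = FALSE))
    bHet <- bindingMatrix(buildNetwork(calls, lr, heteromericMode = TRUE))
    common <- intersect(rownames(bInd), rownames(bHet))
    expect_true(all(bHet[common, colnames(bInd)] <=
                    bInd[common, , drop = FALSE]))
})

test_that("network build is invariant to input row order", {
    d <- syntheticDesign(seed = 71L, nLigandGenes = 8L,
                         nReplicatesPerType = 3L)
    dat <- generateExpression(d)
    lr <- generateLRTable(d)
    calls <- callOverexpressed(dat, lr)
    p <- interactions(lr)
    set.seed(1); perm <- sample(nrow(p))
    lrPerm <- LRInteractionTable(p$ligand[perm], p$receptor[perm],
                                 confidence = p$confidence[perm])
    n1 <- buildNetwork(calls, lr)
    n2 <- buildNetwork(calls, lrPerm)
    lig <- ligandNodes(n1)
    expect_setequal(lig, ligandNodes(n2))
    expect_equal(productionMatrix(n1)[, lig],
                 productionMatrix(n2)[, lig])
    expect_equal(bindingMatrix(n1)[lig, ], bindingMatrix(n2)[lig, ])
})

test_that("degree ranking counts ligands, not receptor species", {
    calls <- makeCalls(
        ligands = list(T1 = c("L1", "L2", "L3"), T2 = character(0)),
        receptors = list(T1 = character(0), T2 = c("R1", "R2")))
    lr <- LRInteractionTable(ligand = c("L1", "L2", "L3", "L1"),
                             receptor = c("R1", "R2", "R1", "R2"))
    net <- buildNetwork(calls, lr, includeOthers = FALSE)
    rk <- rankCellsByDegree(net)
    expect_equal(rk$n_produced_ligands[rk$cell == "T1"], 3L)
    # T2 binds L1 (2 species), L2, L3 -> 3 ligands
    expect_equal(rk$n_bound_ligands[rk$cell == "T2"], 3L)
    empty <- new("CCCNetwork", cellNodes = character(0),
                 ligandNodes = character(0),
                 production = matrix(0, 0, 0), binding = matrix(0L, 0, 0),
                 heteromericMode = FALSE)
    expect_equal(nrow(rankCellsByDegree(empty)), 0L)
})

test_that("exports carry the bipartite structure", {
    calls <- makeCalls(ligands = list(T1 = "LX"),
                       receptors = list(T2 = c("R1", "R2")))
    lr <- LRInteractionTable(ligand = c("LX", "LX"),
                             receptor = c("R1", "R2"))
    net <- buildNetwork(calls, lr, includeOthers = FALSE)
    g <- asIgraph(net)
    expect_setequal(igraph::V(g)$kind[igraph::V(g)$name == "LX"], "ligand")
    expect_equal(sum(igraph::E(g)$edge_type == "binding"), 1L)
    expect_equal(igraph::E(g)$weight[igraph::E(g)$edge_type == "binding"],
                 2)
    gml <- withr::local_tempfile(fileext = ".graphml")
    writeNetworkGraphML(net, gml)
    expect_true(file.size(gml) > 0)
    el <- withr::local_tempfile(fileext = ".tsv")
    writeNetworkEdgeList(net, el)
    df <- read.delim(el)
    expect_setequal(df$edge_type, c("production", "binding"))
})
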