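# phylopaint

Batch styling and SVG rendering of phylogenetic and taxonomic trees, driven
by plain tab-separated mapping files, plus a color-gradient generator that
turns count tables into per-taxon colors.

## The problem

Microbial ecology and phylogenomics routinely produce trees with hundreds to
millions of leaves, each carrying rich per-taxon metadata (host phylum,
sample abundances, test p-values, environmental measurements). Annotating
such trees by hand in a GUI is slow and error-prone, and scripting one-off
figures takes programming effort each time. `phylopaint` makes tree
decoration *data-driven*: you describe the styling in a tab-separated
mapping file — one row per leaf-name pattern, one column per style — and the
package applies it, propagates it up the tree so uniformly styled clades are
visually contiguous, and renders the result to standalone SVG. A companion
gradient generator reduces an OTU-style count table to one color per
observation so that quantitative structure (abundance, evenness, ordination)
can be painted directly onto the tree.

Everything is computed locally in R with deterministic output, so figures
are reproducible and nothing leaves your machine.

## What it computes

**Layouts.** Rectangular and circular layouts follow the cluster-layout
convention: leaves get transverse positions 0, 1, 2, … in depth-first order,
an inner node sits at the midpoint of its extreme children, and the
longitudinal axis is cumulative branch length (or aligned tips for
cladograms). The circular layout maps the transverse axis linearly onto
angles in a configurable sweep. The radial layout is the equal-leaf-wedge
algorithm: the root owns the wedge [0, 2π); each child *w* of *v* is
allocated a consecutive sub-wedge of width

    2π · leaves(w) / leaves(root)

and is placed at position(v) + ℓ(w)·(cos τ_w, sin τ_w), where ℓ(w) is the
branch length and τ_w the wedge midpoint. All traversals are iterative and
vectorised — a 1,000,000-leaf tree parses and lays out in well under a
minute.

**Style propagation.** For each style field independently, an inner node
receives value *v* iff *every* descendant leaf has effective value *v*
(absence of a value counts as a value); otherwise it keeps the default.
Uniformly annotated clades therefore color all the way to their ancestral
node.

**Reductions.** Given a count table with M observations and N variables
(c_ij = value of observation i for variable j), observation i can be scored
by

* its mean, μ_i = (Σ_j c_ij)/N (a `sum = TRUE` flag uses the plain row sum);
* Pielou's evenness, E_i = H_i / H_max with
  H_i = −Σ_j p_ij log₂ p_ij, p_ij = c_ij / Σ_j c_ij, H_max = log₂ N;
* its PC-1 score from a principal components analysis via the singular
  value decomposition X = USV' of the column-centered (optionally scaled)
  matrix, with a fixed sign convention (the largest-magnitude loading in
  V's first column is positive).

Scores are min-max scaled onto [0, 1] and looked up in a gradient — either
piecewise-linear RGB interpolation between color stops (ColorBrewer-style
palettes ship as data) or the cubehelix scheme, computed from Green's
formula with parameters (start, rotations, hue, gamma).

## Worked example

```r
library(phylopaint)

tree <- parse_newick("((A:1,B:2)95:0.5,C:3);")
glance(tree)
#> # A tibble: 1 × 6
#>   n_nodes n_leaves n_inner has_lengths max_depth n_duplicated_leaf_names
#>     <int>    <int>   <int> <lgl>           <dbl>                   <int>
#> 1       5        3       2 TRUE                3                       0

# evenness of a skewed row: p = (0.5, 0.25, 0.25), H = 1.5 bits,
# E = 1.5 / log2(3)
reduce_evenness(parse_count_table("otu\ts1\ts2\ts3\nx\t2\t1\t1"))
#> # A tibble: 1 × 3
#>   name  raw_score scaled
#>   <chr>     <dbl>  <dbl>
#> 1 x         0.946    0.5

# means 1, 2, 3 on a black-to-white gradient: endpoints plus the
# half-up-rounded midpoint gray
tab <- parse_count_table("otu\ta\nx\t1\ny\t2\nz\t3")
apply_gradient(reduce_mean(tab), gradient_stops(c("#000000", "#ffffff")))
#> # A tibble: 3 × 4
#>   name  raw_score scaled color
#>   <chr>     <dbl>  <dbl> <chr>
#> 1 x             1    0   #000000
#> 2 y             2    0.5 #808080
#> 3 z             3    1   #ffffff

# style, propagate, and render: A and B share a color, so their ancestor
# inherits it; the mixed root stays default
rules <- parse_mapping("name\tbranch_color\nA\t#ff0000\nB\t#ff0000\nC\t#0000ff")
styles <- propagate_styles(tree, resolve_leaf_styles(tree, rules))
svg <- render_svg(tree, layout_rectangular(tree), styles = styles,
                  decorations = support_decorations(tree, 95, 70))
```

The raw score 0.946 is E = 1.5/log₂3: the row is fairly but not perfectly
even. In the gradient table, `scaled` is the min-max position of each mean
and `color` the gradient evaluated there (127.5 rounds half-up to 128 =
`80` hex). The SVG contains one `path` per edge, one `text` per leaf, and a
filled circle on the 95-support node.

The same pipelines are scriptable from a shell:

```sh
phylopaint synth    --leaves 50 --seed 1 --out-dir demo
phylopaint gradient --table demo/counts.tsv --out demo/colors.tsv \
                    --mode evenness --gradient viridis
phylopaint render   --tree demo/tree.nwk --mapping demo/colors.tsv \
                    --layout circular --out demo/tree.svg
```

(`phylopaint` here is the wrapper at `inst/exec/phylopaint`, installed under
`system.file("exec", ...)`; calling `phylopaint::cli_main()` is
equivalent.)

## Scope

Input is Newick only (no NEXUS/PhyloXML), trees are used as rooted and never
rerooted, patterns are plain substrings (no regex), and output is SVG 1.1
(no PDF/PNG, legends, or label-collision handling). See the methods
vignette (`vignettes/phylopaint-methods.Rmd`) for the model details, the
tunable parameters, and known limitations.
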