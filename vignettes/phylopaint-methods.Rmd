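---
title: "Tree styling, layouts, and color reductions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree styling, layouts, and color reductions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopaint)
```

`phylopaint` decorates rooted trees from tab-separated metadata and reduces
count tables to colors. This vignette is the package's account of the
procedures it implements, the parameters that matter, and the design
decisions taken where more than one reasonable choice existed.

## The tree model

A tree is a flat tibble of nodes in preorder: node 1 is the root, every
parent id is smaller than its children's ids, and sibling order equals id
order. This representation was chosen over a recursive node structure
because every algorithm in the package then becomes an iterative sweep over
integer vectors — there is no recursion anywhere, so tree depth never hits
R's call-stack limit, and million-leaf trees are handled in seconds.

The Newick dialect: single-quoted labels with `''` escapes are supported,
`[...]` comments are discarded, and underscores are *not* converted to
spaces. Keeping underscores verbatim is deliberate: mapping files match
against leaf names, and silently rewriting `OTU_1` to `OTU 1` would break
exact matching against the names users see in their FASTA headers and
FastTree/RAxML output. Multifurcations and single-child nodes are kept as
parsed, and no rerooting is offered — support labels stay attached to the
inner node they were parsed on, which is only safe because the topology is
never re-rooted underneath them. Branch lengths must be finite and
non-negative; a tree in which any non-root edge lacks a length is treated
as a cladogram downstream.

Duplicate leaf names are legal (they occur in real OTU tables); they are
reported with a warning, and every matching leaf is styled independently.

## Layouts

**Rectangular.** Leaves take transverse coordinates 0, 1, 2, … in
depth-first order; an inner node sits at the midpoint of its *extreme*
children. The midpoint-of-extremes rule matches the cluster-layout
convention familiar from dendrogram drawing; a `midpoint_extremes = FALSE`
flag switches to the mean of all children for users who prefer that look.
The longitudinal coordinate is cumulative branch length in phylogram mode;
in cladogram mode every leaf is aligned at the maximum hop depth and inner
nodes sit at their hop depth. Requesting branch lengths on a lengthless
tree falls back to the cladogram with a recorded warning rather than an
error, because partially annotated trees are common and a drawn tree with a
warning is more useful than a refusal.

**Circular.** The rectangular transverse axis is mapped linearly onto
angles — leaf $k$ of $n$ gets angle $k \cdot s/n$ for a sweep $s$ — and the
longitudinal axis becomes the radius. The default sweep is 360°; smaller
sweeps leave a readable gap. Angles are radians, measured counterclockwise
from the positive x axis; the renderer rotates the figure so the first leaf
sits at the top. These conventions are arbitrary but fixed, so coordinates
are testable to the last bit.

**Radial.** The equal-leaf-wedge algorithm: the root owns $[0, 2\pi)$; in
preorder each child $w$ is allocated a consecutive sub-wedge of width
$2\pi \cdot \mathrm{leaves}(w)/\mathrm{leaves}(\mathrm{root})$ starting at
its parent's wedge start, and is displaced from its parent by its branch
length along the wedge-midpoint angle. Two properties follow directly and
are enforced by tests: every parent–child distance equals the child's
branch length, and sibling wedges exactly partition the parent wedge. For
cladograms the radial layout substitutes unit branch lengths (with a
warning); this keeps the algorithm total without inventing a second layout
mode.

Zero-length branches are allowed and may produce coincident points; the
renderer still draws labels there.

## Mapping files and style propagation

The column vocabulary (`branch_color`, `branch_width`, `label_color`,
`label_font_size`, `new_name`, `leaf_dot_color`, `leaf_dot_size`,
`bar<k>_height`, `bar<k>_color`, `arc_color`) covers every stylable aspect:
branches, leaf labels, leaf dots, bar series, and arcs. Matching is exact
or plain-substring — not regular expressions — because accession-style
names are full of regex metacharacters and a literal substring is what
users almost always mean. Matching is case-sensitive by default with an
`ignore_case` opt-in; the default is documented rather than inferred from
any reference behaviour. When several rules hit one leaf they apply in file
order, later rules overriding earlier ones field by field, so a generic
rule can be refined by a later specific one. `new_name` is applied only at
render time; matching always uses the original names, so renaming cannot
change which rules fire.

Propagation gives an inner node a style value iff all of its descendant
leaves share it, with "unstyled" counting as a value. It is computed in one
post-order pass and is idempotent. The consequence worth knowing: a single
unmatched leaf inside an otherwise uniform clade keeps that clade's
ancestors at the default — that is the intended reading of "all descendants
agree", and the test suite pins it with a brute-force oracle that
enumerates every node's descendant leaves by walking ancestor chains.

Support decorations threshold numeric inner labels: filled circle at
`s >= filled_min` (default 95), open circle at `open_min <= s < filled_min`
(default 70), nothing otherwise. The defaults assume percent-scale
bootstrap values; users with proportions pass 0.95/0.70 — the rule is
scale-agnostic.

## Count-table reductions

The mean reduction scores each observation by its row mean. A `sum = TRUE`
variant scores by the plain row sum instead; the two differ by the constant
factor $N$, so after min-max scaling they color identically — the flag
exists for users who want the raw scores themselves on the sum scale.

Pielou evenness is
$E_i = -\sum_j p_{ij}\log_2 p_{ij} \,/\, \log_2 N$ with
$p_{ij} = c_{ij}/\sum_j c_{ij}$ and the $0\log 0 = 0$ convention. It is
undefined for $N = 1$ (the denominator is zero) and for zero-sum or
negative rows; these are errors naming the offending observation rather
than silent NAs, because a gradient built on partly-undefined scores would
be misleading. $E_i$ is invariant to positive row scaling and column
permutation, equals 1 exactly on uniform rows, and is strictly below 1
otherwise; all three properties are tested on random rows.

The projection reduction is PCA via the SVD: columns of $X$ are centered
and optionally divided by their sample standard deviation ($M-1$
denominator, the standard unbiased choice); zero-variance columns are left
centered with a warning, since dividing by zero would be worse than
under-weighting a constant column. From $X = USV^\top$, observation $i$'s
score is row $i$ of the first column of $US$. The SVD sign ambiguity is
resolved by requiring the largest-magnitude entry of $V$'s first column to
be positive (earliest such entry on ties); this makes scores deterministic
across repeated runs and row orderings, which matters because a flipped
sign would silently reverse the color gradient. Scores are then min-max
scaled, so any uniform rescaling of the score axis is irrelevant — only the
ordering and relative spacing survive into the colors.

Min-max scaling maps the score range onto $[0, 1]$, with the all-equal
degenerate case mapping to 0.5 (the gradient midpoint) rather than an
arbitrary endpoint. Rank or quantile scaling was deliberately not used:
min-max preserves relative distances, which is what a sequential color
gradient is read as encoding.

## Color math

Stop gradients interpolate linearly per RGB channel between bracketing
stops. Interpolation is in raw RGB rather than a perceptual space (Lab,
HCL): the tradeoff is known — RGB interpolation can pass through muddy
midpoints — but it makes every output color exactly computable by hand,
which the test suite exploits (`#000000` → `#ff0000` at λ = 0.5 is exactly
`#800000`). Channel quantisation rounds half-up (127.5 → 128), a fixed rule
chosen over banker's rounding so results do not depend on parity.

Cubehelix follows Green's formula: with
$\phi = 2\pi(s/3 + r\lambda)$, $g = \lambda^\gamma$ and
$a = h\,g(1-g)/2$,

$$R = g + a(-0.14861\cos\phi + 1.78277\sin\phi)$$
$$G = g + a(-0.29227\cos\phi - 0.90649\sin\phi)$$
$$B = g + a(1.97294\cos\phi)$$

Defaults are $s = 0.5$, $r = -1.5$, $h = 1$, $\gamma = 1$ — the original
scheme's defaults. The helix can leave the RGB cube, so channels are
clamped to $[0,1]$ before quantisation. Endpoints are structural: $g = 0$
forces black at $\lambda = 0$, and with $\gamma = 1$, $g = 1$ forces white
at $\lambda = 1$.

Named palettes (a viridis-style sequence, ColorBrewer-style diverging
lists, two-color ramps) are data — plain stop lists validated by the same
stops invariant as user-supplied gradients — not special-cased code.

## Rendering

The renderer emits SVG 1.1 by direct string construction with a fixed
element order and all coordinates formatted at 4 decimals, so identical
inputs produce byte-identical documents — golden-file tests then work
across platforms. Edges are right-angle elbows in rectangular mode (the
idiom of cluster layouts), a radial segment plus a circular arc in circular
mode, and straight segments in radial mode. Bars are drawn beyond the leaf
tips (rectangles, or outward annular wedges in circular mode), scaled so
the largest |height| in each series renders at exactly `bar_max_length`;
zero heights draw nothing, and negative heights draw at |height| in the
same direction, optionally flagged by a second color (`bar_negative_color`)
for ratio-style series. Arcs are fixed-thickness bands spanning each styled
leaf's slot. Bars and arcs are not drawn in the radial layout, which has no
leaf-aligned band to attach them to. Label rotation in circular/radial
modes flips text on the left half for readability; there are no font
metrics, so label collision avoidance is out of scope.

## The synthetic generator

`gen_tree()` grows trees by sequential random attachment — each new leaf
splits a uniformly chosen existing edge — with i.i.d. uniform(0, 1) branch
lengths. The branch-length law matches the million-leaf random-tree stress
convention (`runif` defaults); sequential attachment was chosen over
Yule/coalescent models because it is simple, exercises unbalanced
topologies, and the styling and layout code is indifferent to the
generating process. `gen_counts()` draws Poisson(10) counts by
inverse-transform sampling on the seeded uniform stream and redraws
all-zero rows so evenness is always defined. `gen_mapping()` plants a
uniformly colored clade inside an otherwise random coloring, giving
propagation tests a known positive case.

What the generator does *not* emulate: real branch-length distributions
(no rate variation or ultrametricity), overdispersed or compositional count
structure, and metadata correlated with topology. Passing tests therefore
demonstrate algorithmic correctness and scale behaviour, not biological
realism of any example figure.

## Numerical choices and problem sizes

Radial geometry and PCA centering are asserted to 1e−9; evenness
invariances to 1e−12 — comfortably above double-precision noise, far below
anything visible in a figure. The verification suites run at fixed sizes
chosen as this package's own study conditions: the layout stress case at
1,000,000 leaves, round-trip identity on 500 random trees, propagation and
radial geometry on 200 trees each (≤ 200 leaves), evenness invariances on
1,000 random rows, PCA optimality on 100 random tables against 1,000
random unit projections apiece, and rendering laws on 100 trees.

## Known limitations

* Newick only; no NEXUS, PhyloXML, or NeXML, and no rerooting or
  ladderizing — reroot upstream if the rooting matters.
* Substring matching is literal; there is no regex or MRCA-addressed
  clade annotation format.
* RGB-space interpolation is perceptually non-uniform between distant
  stops.
* SVG output only; no raster export, legends, or opacity, and label
  overlap is the user's responsibility.
* The biom formats are not parsed; export a classic-style TSV first.
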