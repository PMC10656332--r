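[
  {
    "name": "three_items",
    "file": "three_items.tsv",
    "J": 3,
    "N": 130,
    "support_cells": 7
  },
  {
    "name": "two_cell",
    "file": "two_cell.tsv",
    "J": 3,
    "N": 130,
    "support_cells": 2
  },
  {
    "name": "single_cell_2x2",
    "file": "single_cell_2x2.tsv",
    "J": 2,
    "N": 1,
    "support_cells": 1
  },
  {
    "name": "diagonal_2x2",
    "file": "diagonal_2x2.tsv",
    "J": 2,
    "N": 2,
    "support_cells": 2
  },
  {
    "name": "perfect_guttman",
    "file": "perfect_guttman.tsv",
    "J": 2,
    "N": 90,
    "support_cells": 3
  }
]
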