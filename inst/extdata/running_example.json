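{
  "schema": "bnsketch-sketch/1",
  "variables": [
    "v1",
    "v2",
    "v3"
  ],
  "influences": [
    {
      "regulator": "v1",
      "target": "v1"
    },
    {
      "regulator": "v3",
      "target": "v1"
    },
    {
      "regulator": "v1",
      "target": "v2"
    },
    {
      "regulator": "v1",
      "target": "v3"
    },
    {
      "regulator": "v2",
      "target": "v3"
    }
  ],
  "symbols": {
    "f": 1,
    "g": 1,
    "h": 2
  },
  "update_expressions": {
    "v1": "v1 & f(v3)",
    "v2": "g(v1)",
    "v3": "h(v1, v2)"
  },
  "properties": [
    {
      "target": "v1",
      "property": "(essential(v3)) & (negative(v3))"
    },
    {
      "target": "v3",
      "property": "((essential(v1)) & (essential(v2))) & (positive(v1))"
    }
  ],
  "hctl": [
    "3{c}: @{c}: 3{a}: 3{b}: (EF {a} & EF {b}) & (@{a}: !{y}: AG EF {y}) & (@{b}: (!{z}: AG EF {z}) & ~(EF {a}))",
    "3{x}: @{x}: ((~v1 & ~v2) & ~v3) & (!{y}: AG EF {y})",
    "3{x}: @{x}: ((v1 & v2) & ~v3) & (!{y}: AG EF {y})"
  ]
}
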