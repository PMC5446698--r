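{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Parse result for one scientific name-string",
  "type": "object",
  "required": ["name_string_id", "parsed", "parser_version", "verbatim",
               "hybrid", "surrogate", "virus", "details", "positions",
               "quality_warnings"],
  "properties": {
    "name_string_id": {
      "type": "string",
      "pattern": "^[0-9a-f]{8}-[0-9a-f]{4}-5[0-9a-f]{3}-[0-9a-f]{4}-[0-9a-f]{12}$"
    },
    "parsed": {"type": "boolean"},
    "quality": {"type": "integer", "enum": [1, 2, 3]},
    "parser_version": {"type": "string"},
    "verbatim": {"type": "string"},
    "normalized": {"type": "string"},
    "canonical_name": {"type": "string"},
    "hybrid": {"type": "boolean"},
    "surrogate": {"type": "boolean"},
    "virus": {"type": "boolean"},
    "details": {
      "type": "array",
      "items": {"$ref": "#/definitions/detail"}
    },
    "positions": {
      "type": "array",
      "items": {
        "type": "array",
        "minItems": 3,
        "maxItems": 3,
        "items": [
          {"type": "string",
           "enum": ["genus", "subgenus", "uninomial", "specific_epithet",
                    "infraspecific_epithet", "rank", "author_word", "year",
                    "annotation", "hybrid_sign"]},
          {"type": "integer", "minimum": 0},
          {"type": "integer", "minimum": 1}
        ]
      }
    },
    "quality_warnings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["code", "message", "level"],
        "properties": {
          "code": {"type": "string"},
          "message": {"type": "string"},
          "level": {"type": "integer", "enum": [2, 3]}
        }
      }
    }
  },
  "definitions": {
    "author_team": {
      "type": "object",
      "required": ["authors"],
      "properties": {
        "authors": {"type": "array", "items": {"type": "string"}},
        "ex_authors": {"type": "array", "items": {"type": "string"}},
        "year": {"type": "string"}
      }
    },
    "authorship": {
      "type": "object",
      "required": ["verbatim"],
      "properties": {
        "verbatim": {"type": "string"},
        "basionym_authorship": {"$ref": "#/definitions/author_team"},
        "combination_authorship": {"$ref": "#/definitions/author_team"}
      }
    },
    "epithet": {
      "type": "object",
      "required": ["value"],
      "properties": {
        "value": {"type": "string"},
        "rank": {"type": "string"},
        "authorship": {"$ref": "#/definitions/authorship"}
      }
    },
    "detail": {
      "type": "object",
      "properties": {
        "genus": {"type": "string"},
        "subgenus": {"type": "string"},
        "uninomial": {"type": "string"},
        "rank": {"type": "string"},
        "subuninomial": {"type": "string"},
        "specific_epithet": {"$ref": "#/definitions/epithet"},
        "infraspecific_epithets": {
          "type": "array",
          "items": {"$ref": "#/definitions/epithet"}
        },
        "authorship": {"$ref": "#/definitions/authorship"},
        "annotation": {"type": "string"},
        "ignored_tail": {"type": "string"}
      }
    }
  }
}
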