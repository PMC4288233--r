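<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema of the query-task XML dialect (version 1.0).

     The dialect carries exactly the information the query engine
     consumes from a flowchart export: node class, verbatim criterion
     strings, edges, selection flags and mutually-exclusive child
     priorities. It is a stand-in dialect; native Protege/GLIF3.5
     exports are not parsed. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="queryTask">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="node" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="criterion" type="xs:string"
                          minOccurs="0" maxOccurs="unbounded"/>
              <xs:element name="priority" type="xs:string"
                          minOccurs="0" maxOccurs="unbounded"/>
            </xs:sequence>
            <xs:attribute name="id" type="xs:string" use="required"/>
            <xs:attribute name="name" type="xs:string"/>
            <xs:attribute name="class" use="required">
              <xs:simpleType>
                <xs:restriction base="xs:string">
                  <xs:enumeration value="action"/>
                  <xs:enumeration value="decision"/>
                  <xs:enumeration value="branch"/>
                  <xs:enumeration value="synchronization"/>
                  <xs:enumeration value="patient_state"/>
                </xs:restriction>
              </xs:simpleType>
            </xs:attribute>
            <xs:attribute name="selected" type="xs:boolean" default="true"/>
            <xs:attribute name="mutuallyExclusive" type="xs:boolean"
                          default="false"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="edge" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="from" type="xs:string" use="required"/>
            <xs:attribute name="to" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="version" type="xs:string" use="required"/>
      <xs:attribute name="name" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
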